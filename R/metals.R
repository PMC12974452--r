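#' Geometric center of the protein body
#'
#' Unweighted mean of the protein heavy-atom coordinates (waters and ions
#' excluded).
#'
#' @param model a `structure_model` with at least one protein atom.
#' @return length-3 numeric vector, Angstrom.
#' @export
geometric_center <- function(model) {
  pm <- protein_coords(model)
  if (!nrow(pm)) stop("model has no protein atoms")
  colMeans(pm)
}

#' Ion distances from the assembly geometric center, per condition
#'
#' For each condition, the distance of every matching ion to that
#' condition's protein geometric center: the radial displacement of
#' channel-bound ions across pH.
#'
#' @param models list of `structure_model`s (one per condition).
#' @param element ion element symbol, e.g. `"FE"` or `"MG"`.
#' @return data.frame with one row per ion (`condition`, `chain`,
#'   `residue_id`, `occupancy`, `distance`) plus a `summary` attribute
#'   (per-condition mean, sd, n).
#' @export
ion_center_distances <- function(models, element) {
  element <- toupper(element)
  rows <- lapply(models, function(m) {
    ions <- which(is_ion(m) & m$atoms$element == element)
    if (!length(ions)) return(NULL)
    ctr <- geometric_center(m)
    p <- as.matrix(m$atoms[ions, c("x", "y", "z")])
    data.frame(condition = m$condition_label,
               chain = m$atoms$chain_id[ions],
               residue_id = m$atoms$residue_id[ions],
               occupancy = m$atoms$occupancy[ions],
               distance = sqrt(rowSums(sweep(p, 2, ctr)^2)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("element ", element, " absent from every model")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  summ <- aggregate(distance ~ condition, out,
                    function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  attr(out, "summary") <- summ
  out
}

#' Waters near an ion, tagged by persistence
#'
#' Lists the water observations of the ion's condition within `shell` of
#' the ion position, sorted by distance, each carrying its cluster's
#' persistence category and a hydrogen-bond-range flag for distances at or
#' below `hbond_distance`.
#'
#' @param ion_position length-3 position of the ion, Angstrom (common
#'   frame).
#' @param condition condition label whose realized waters to search.
#' @param wss a `water_site_set` with persistence categories.
#' @param shell search radius, Angstrom (default 5).
#' @param hbond_distance hydrogen-bond-range threshold, Angstrom.
#' @return data.frame (`distance`, `category`, `cluster_id`, `hbond`),
#'   zero rows when nothing is within the shell.
#' @export
ion_water_contacts <- function(ion_position, condition, wss, shell = 5,
                               hbond_distance = 3.5) {
  mem <- wss$members[wss$members$condition == condition, , drop = FALSE]
  empty <- data.frame(distance = numeric(0), category = character(0),
                      cluster_id = integer(0), hbond = logical(0))
  if (!nrow(mem)) return(empty)
  d <- sqrt(colSums((t(as.matrix(mem[, c("x", "y", "z")])) -
                       as.numeric(ion_position))^2))
  keep <- d <= shell
  if (!any(keep)) return(empty)
  cat_of <- wss$sites$category[match(mem$cluster_id[keep],
                                     wss$sites$cluster_id)]
  out <- data.frame(distance = d[keep], category = cat_of,
                    cluster_id = mem$cluster_id[keep],
                    hbond = d[keep] <= hbond_distance,
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
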