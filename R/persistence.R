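# all index pairs (i < j) with euclidean distance strictly below cutoff,
# found via a cell list so the search scales with occupancy, not n^2
neighbor_pairs <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  cell <- floor(sweep(pos, 2, apply(pos, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  cells <- split(seq_len(n), key)
  coords <- do.call(rbind, strsplit(names(cells), ",", fixed = TRUE))
  coords <- matrix(as.integer(coords), ncol = 3)
  lookup <- seq_along(cells)
  names(lookup) <- names(cells)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    idx_i <- cells[[ci]]
    nb_keys <- paste(coords[ci, 1] + offs[, 1], coords[ci, 2] + offs[, 2],
                     coords[ci, 3] + offs[, 3], sep = ",")
    nb <- lookup[nb_keys]
    nb <- nb[!is.na(nb) & nb > ci]  # each unordered cell pair visited once
    pr <- list()
    # intra-cell pairs
    if (length(idx_i) > 1L) {
      for (a in seq_len(length(idx_i) - 1L)) {
        i <- idx_i[a]
        j <- idx_i[(a + 1L):length(idx_i)]
        dj <- sqrt(colSums((t(pos[j, , drop = FALSE]) - pos[i, ])^2))
        hit <- j[dj < cutoff]
        if (length(hit)) pr[[length(pr) + 1L]] <- cbind(i, hit)
      }
    }
    # cross pairs with every forward neighbour cell, all combinations
    cand <- unlist(cells[nb], use.names = FALSE)
    if (length(cand)) {
      for (i in idx_i) {
        dj <- sqrt(colSums((t(pos[cand, , drop = FALSE]) - pos[i, ])^2))
        hit <- cand[dj < cutoff]
        if (length(hit)) pr[[length(pr) + 1L]] <- cbind(i, hit)
      }
    }
    if (length(pr)) out[[ci]] <- do.call(rbind, pr)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

#' Cluster water oxygens across superposed models
#'
#' Pools all water oxygens of an ensemble of models sharing a common
#' reference frame and groups them by single-linkage agglomeration: two
#' waters link when their distance is strictly below `cutoff`, and clusters
#' are the connected components of the link graph. Each cluster is a
#' candidate water *site*; its persistence category follows from how many
#' distinct conditions contribute members: `lone` (one condition),
#' `persistent` (at least two), `most_persistent` (all conditions in the
#' ensemble).
#'
#' @param models list of superposed `structure_model`s (see [superpose()]
#'   and [mark_superposed()]); condition labels must be unique.
#' @param cutoff Angstrom linkage cutoff (default 1.0).
#' @param check_frame error if a model lacks the common-frame flag.
#' @return A `water_site_set`: list with `sites` (one row per cluster:
#'   `cluster_id`, centroid `x,y,z`, `n_members`, `n_conditions`,
#'   `category`) sorted by descending `n_conditions` then centroid order,
#'   `members` (one row per water observation with its `cluster_id`), and
#'   `conditions` (the ensemble's label set).
#' @export
cluster_waters <- function(models, cutoff = 1.0, check_frame = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  labels <- vapply(models, function(m) m$condition_label, character(1))
  if (anyDuplicated(labels))
    stop("condition labels must be unique within an ensemble")
  if (check_frame && !all(vapply(models, is_superposed, logical(1))))
    stop("all models must be superposed to a common frame ",
         "(use superpose()/apply_transform(), mark_superposed() for the ",
         "reference, or check_frame = FALSE)")
  obs <- do.call(rbind, lapply(models, function(m) {
    w <- which(is_water_oxygen(m))
    if (!length(w)) return(NULL)
    data.frame(condition = m$condition_label,
               source_residue_id = m$atoms$residue_id[w],
               occupancy = m$atoms$occupancy[w],
               x = m$atoms$x[w], y = m$atoms$y[w], z = m$atoms$z[w],
               stringsAsFactors = FALSE)
  }))
  if (is.null(obs) || nrow(obs) == 0L)
    stop("ensemble contains no water oxygens")
  pos <- as.matrix(obs[, c("x", "y", "z")])
  pairs <- neighbor_pairs(pos, cutoff)
  g <- igraph::make_empty_graph(n = nrow(obs), directed = FALSE)
  if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  n_total <- length(models)
  cid <- as.integer(comp)
  cx <- tapply(obs$x, cid, mean); cy <- tapply(obs$y, cid, mean)
  cz <- tapply(obs$z, cid, mean)
  ncond <- tapply(obs$condition, cid, function(v) length(unique(v)))
  nmem <- tabulate(cid)
  sites <- data.frame(cluster_id = as.integer(names(cx)),
                      x = as.numeric(cx), y = as.numeric(cy),
                      z = as.numeric(cz),
                      n_members = nmem[as.integer(names(cx))],
                      n_conditions = as.integer(ncond),
                      stringsAsFactors = FALSE)
  sites$category <- persistence_category(sites$n_conditions, n_total)
  ord <- order(-sites$n_conditions, sites$x, sites$y, sites$z)
  sites <- sites[ord, , drop = FALSE]
  # renumber clusters in the deterministic output order
  remap <- setNames(seq_len(nrow(sites)), sites$cluster_id)
  sites$cluster_id <- seq_len(nrow(sites))
  obs$cluster_id <- as.integer(remap[as.character(cid)])
  rownames(sites) <- rownames(obs) <- NULL
  structure(list(sites = sites, members = obs, conditions = labels,
                 cutoff = cutoff),
            class = "water_site_set")
}

persistence_category <- function(n_conditions, n_total) {
  ifelse(n_conditions >= n_total & n_total > 1L, "most_persistent",
         ifelse(n_conditions >= 2L, "persistent", "lone"))
}

#' @export
print.water_site_set <- function(x, ...) {
  tab <- table(factor(x$sites$category,
                      levels = c("lone", "persistent", "most_persistent")))
  cat(sprintf("<water_site_set> %d sites from %d waters across %d conditions\n",
              nrow(x$sites), nrow(x$members), length(x$conditions)))
  cat(sprintf("  lone %d | persistent %d | most_persistent %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Persistence summary of a clustered water ensemble
#'
#' Tabulates, per condition, how many of its water observations fall in
#' lone clusters versus persistent clusters (shared with at least one other
#' condition), and the global histogram of clusters by the number of
#' conditions they span.
#'
#' @param wss a `water_site_set` from [cluster_waters()].
#' @param n_total_conditions total number of conditions; defaults to the
#'   number of labels recorded in `wss`.
#' @return list with `per_condition` (data.frame: `condition`, `lone`,
#'   `persistent`) and `histogram` (named integer vector over
#'   `1..n_total_conditions`).
#' @export
classify_persistence <- function(wss, n_total_conditions = length(wss$conditions)) {
  if (n_total_conditions < 1L) stop("n_total_conditions must be >= 1")
  unknown <- setdiff(unique(wss$members$condition), wss$conditions)
  if (length(unknown))
    stop("cluster member references unknown condition: ",
         paste(unknown, collapse = ", "))
  ncond_of <- wss$sites$n_conditions[match(wss$members$cluster_id,
                                           wss$sites$cluster_id)]
  per <- lapply(wss$conditions, function(lab) {
    sel <- wss$members$condition == lab
    data.frame(condition = lab,
               lone = sum(sel & ncond_of == 1L),
               persistent = sum(sel & ncond_of >= 2L),
               stringsAsFactors = FALSE)
  })
  hist <- tabulate(wss$sites$n_conditions, nbins = n_total_conditions)
  names(hist) <- as.character(seq_len(n_total_conditions))
  list(per_condition = do.call(rbind, per), histogram = hist)
}

#' Assign each water site its nearest protein residue
#'
#' For every cluster centroid, finds the protein heavy atom nearest to it
#' in `model` (normally the ensemble's reference-condition model). If that
#' distance is at most `cutoff` the owning residue is recorded; otherwise
#' the site stays unassigned (a value, not an error).
#'
#' @param wss a `water_site_set`.
#' @param model a superposed `structure_model` supplying the protein.
#' @param cutoff Angstrom (default 3.6).
#' @return `wss` with columns `nearest_residue_name`, `nearest_residue_id`,
#'   `nearest_chain`, `nearest_distance` added to `sites` (NA when
#'   unassigned).
#' @export
assign_nearest_residue <- function(wss, model, cutoff = 3.6) {
  keep <- is_protein_atom(model) & model$atoms$element != "H"
  pa <- model$atoms[keep, , drop = FALSE]
  pm <- t(as.matrix(pa[, c("x", "y", "z")]))
  s <- wss$sites
  nm <- character(nrow(s)); id <- integer(nrow(s))
  ch <- character(nrow(s)); dd <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    d <- sqrt(colSums((pm - c(s$x[i], s$y[i], s$z[i]))^2))
    j <- which.min(d)
    if (d[j] <= cutoff) {
      nm[i] <- pa$residue_name[j]; id[i] <- pa$residue_id[j]
      ch[i] <- pa$chain_id[j]; dd[i] <- d[j]
    } else {
      nm[i] <- NA_character_; id[i] <- NA_integer_
      ch[i] <- NA_character_; dd[i] <- NA_real_
    }
  }
  wss$sites$nearest_residue_name <- nm
  wss$sites$nearest_residue_id <- id
  wss$sites$nearest_chain <- ch
  wss$sites$nearest_distance <- dd
  wss
}

#' Amino-acid preferences of a persistence category
#'
#' Histogram of nearest-residue types over the sites of one category
#' (default the most persistent). Unassigned sites are counted under
#' `"unassigned"`; totals conserve the number of sites considered.
#'
#' @param wss a `water_site_set` with nearest residues assigned.
#' @param category which persistence category to tabulate.
#' @return named integer vector over the 20 amino-acid types (plus any
#'   other residue names encountered) and `"unassigned"`.
#' @export
residue_preferences <- function(wss, category = "most_persistent") {
  if (is.null(wss$sites$nearest_residue_name))
    stop("run assign_nearest_residue() first")
  s <- wss$sites[wss$sites$category == category, , drop = FALSE]
  lev <- unique(c(.AA3, setdiff(stats::na.omit(s$nearest_residue_name), .AA3)))
  res <- factor(ifelse(is.na(s$nearest_residue_name), "unassigned",
                       s$nearest_residue_name),
                levels = c(lev, "unassigned"))
  table(res)
}

#' Exact two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum of the absolute difference between the two empirical CDFs,
#' evaluated exactly on the pooled sorted values (ties handled by stepping
#' both ECDFs at the shared value).
#'
#' @param x,y numeric samples.
#' @return The KS statistic in \[0, 1\].
#' @export
ks_statistic <- function(x, y) {
  x <- sort(x[is.finite(x)]); y <- sort(y[is.finite(y)])
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  z <- sort(unique(c(x, y)))
  Fx <- ecdf(x); Fy <- ecdf(y)
  max(abs(Fx(z) - Fy(z)))
}

#' Nearest water-water distances by persistence category
#'
#' For every realized water in every condition, computes the distance to
#' the nearest *other* water of the same condition, then pools these
#' distances by the persistence category of the cluster the water belongs
#' to. Pairwise KS statistics compare the category distributions.
#'
#' @param wss a `water_site_set` from [cluster_waters()].
#' @return list with `distributions` (per category: `values`, `count`,
#'   `median`, `q1`, `q3`, `degenerate` flag for <2 values) and
#'   `ks_matrix` (3x3, NA where either category is degenerate).
#' @export
nearest_water_distances <- function(wss) {
  mem <- wss$members
  mem$nn_dist <- NA_real_
  for (lab in wss$conditions) {
    idx <- which(mem$condition == lab)
    if (length(idx) < 2L) next
    p <- as.matrix(mem[idx, c("x", "y", "z")])
    dm <- as.matrix(dist(p))
    diag(dm) <- Inf
    mem$nn_dist[idx] <- apply(dm, 1, min)
  }
  cat_of <- wss$sites$category[match(mem$cluster_id, wss$sites$cluster_id)]
  cats <- c("lone", "persistent", "most_persistent")
  distributions <- lapply(cats, function(cc) {
    v <- mem$nn_dist[cat_of == cc & !is.na(mem$nn_dist)]
    list(category = cc, values = v, count = length(v),
         median = if (length(v)) median(v) else NA_real_,
         q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
         q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
         degenerate = length(v) < 2L)
  })
  names(distributions) <- cats
  ks <- matrix(NA_real_, 3, 3, dimnames = list(cats, cats))
  for (i in 1:3) for (j in 1:3) {
    vi <- distributions[[i]]$values; vj <- distributions[[j]]$values
    if (length(vi) >= 2L && length(vj) >= 2L)
      ks[i, j] <- ks_statistic(vi, vj)
  }
  list(distributions = distributions, ks_matrix = ks)
}
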