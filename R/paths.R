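# Accessible mutational pathways on the five-residue hypercube.
#
# An edge is the addition of exactly one wild-type residue (80 edges in
# total); a monotonic path is one of the 5! = 120 orderings of the five
# additions from the minimal enzyme to WT in which every step increases
# activity by strictly more than the chosen fold threshold.

#' All single-residue-addition edges of a landscape
#'
#' @param landscape An \code{ap_landscape}.
#' @param wt_convention WT reference convention; defaults to the
#'   landscape's (path analyses conventionally use the observed WT value).
#' @return Data.frame of the 80 edges with columns \code{from}, \code{to}
#'   (genotype bitstrings), \code{residue} (the residue added),
#'   \code{ratio} (activity(to)/activity(from)), \code{censored}.
#' @export
landscape_edges <- function(landscape, wt_convention = NULL) {
  stopifnot(inherits(landscape, "ap_landscape"))
  from <- character(0); to <- character(0); res <- character(0)
  for (g in all_genotypes()) {
    pres <- genotype_present(g)
    for (r in ap_residues()[!pres]) {
      from <- c(from, g)
      to <- c(to, .genotype_with(g, r, TRUE))
      res <- c(res, r)
    }
  }
  ratio <- landscape_activity(landscape, to, wt_convention) /
    landscape_activity(landscape, from, wt_convention)
  censored <- .is_censored(landscape, from) | .is_censored(landscape, to)
  data.frame(from = from, to = to, residue = res, ratio = ratio,
             censored = censored, stringsAsFactors = FALSE)
}

#' Edges passing a strict fold-increase threshold
#'
#' An edge passes when its activity ratio strictly exceeds
#' \code{threshold}; an edge whose ratio equals the threshold never passes.
#' Censored endpoints are evaluated at their nominal bounds and flagged.
#'
#' @inheritParams landscape_edges
#' @param threshold Positive fold-increase cutoff (strict \code{>}).
#' @return The passing subset of [landscape_edges()].
#' @export
#' @examples
#' nrow(classify_edges(builtin_table1(), 3))
classify_edges <- function(landscape, threshold, wt_convention = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  e <- landscape_edges(landscape, wt_convention)
  e[e$ratio > threshold, , drop = FALSE]
}

# all permutations of seq_len(n), lexicographic
.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Enumerate monotonic (selectively accessible) paths by brute force
#'
#' Examines each of the 120 orderings of the five residue additions from the
#' minimal enzyme to WT; a path is accessible iff every one of its five
#' steps increases activity by strictly more than \code{threshold}-fold.
#'
#' @inheritParams classify_edges
#' @return A \code{path_census}: list with \code{threshold},
#'   \code{wt_convention}, \code{n_paths_total} (120),
#'   \code{n_paths_accessible}, \code{n_edges_passing}, \code{paths} (a list
#'   of accessible residue orderings), and \code{censored_used} (whether any
#'   accessible path crosses a censored record).
#' @export
#' @examples
#' enumerate_monotonic_paths(builtin_table1(), 3)$n_paths_accessible
enumerate_monotonic_paths <- function(landscape, threshold, wt_convention = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  edges <- landscape_edges(landscape, wt_convention)
  key <- paste(edges$from, edges$to)
  pass <- stats::setNames(edges$ratio > threshold, key)
  cens <- stats::setNames(edges$censored, key)
  paths <- list()
  censored_used <- FALSE
  for (perm in .permutations(5L)) {
    g <- "00000"
    ok <- TRUE
    used_cens <- FALSE
    for (i in perm) {
      nxt <- .genotype_with(g, ap_residues()[i], TRUE)
      k <- paste(g, nxt)
      if (!pass[[k]]) { ok <- FALSE; break }
      used_cens <- used_cens || cens[[k]]
      g <- nxt
    }
    if (ok) {
      paths[[length(paths) + 1L]] <- ap_residues()[perm]
      censored_used <- censored_used || used_cens
    }
  }
  structure(list(threshold = threshold,
                 wt_convention = wt_convention %||% attr(landscape, "wt_convention"),
                 n_paths_total = 120L,
                 n_paths_accessible = length(paths),
                 n_edges_passing = sum(edges$ratio > threshold),
                 paths = paths, censored_used = censored_used),
            class = "path_census")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.path_census <- function(x, ...) {
  cat(sprintf(
    "Path census at >%g-fold (WT convention: %s):\n  %d / %d orderings accessible; %d / 80 edges pass\n",
    x$threshold, x$wt_convention, x$n_paths_accessible, x$n_paths_total,
    x$n_edges_passing))
  invisible(x)
}

#' Count accessible paths by dynamic programming
#'
#' Counts the same quantity as [enumerate_monotonic_paths()] without
#' enumerating orderings: accessible-path counts are accumulated per
#' genotype along passing edges in order of the number of residues present.
#'
#' @inheritParams classify_edges
#' @return Integer count of accessible orderings (0..120).
#' @export
count_paths_dp <- function(landscape, threshold, wt_convention = NULL) {
  pass <- classify_edges(landscape, threshold, wt_convention)
  counts <- stats::setNames(numeric(32), all_genotypes())
  counts["00000"] <- 1
  for (g in all_genotypes()) {  # ordered by number present: valid DP order
    if (counts[[g]] == 0) next
    outs <- pass$to[pass$from == g]
    for (h in outs) counts[[h]] <- counts[[h]] + counts[[g]]
  }
  as.integer(counts[["11111"]])
}

#' Path accessibility across thresholds, with borderline-edge sensitivity
#'
#' For each threshold, reports the edge and path census together with the
#' edges whose ratio lies within +/-20\% of the cutoff. Because the source
#' activities are printed to two significant figures, counts at a given
#' cutoff are only as trustworthy as the borderline list is short; the
#' listing makes the sensitivity auditable.
#'
#' @inheritParams classify_edges
#' @param thresholds Numeric vector of fold cutoffs.
#' @return An \code{accessibility_report}: data.frame with one row per
#'   threshold (\code{threshold}, \code{n_edges_passing},
#'   \code{n_paths_accessible}) and a \code{borderline} attribute listing,
#'   per threshold, the edges with \code{ratio} in
#'   \code{[0.8, 1.2] * threshold}.
#' @export
#' @examples
#' accessibility_report(builtin_table1(), c(3, 5))
accessibility_report <- function(landscape, thresholds = c(3, 5),
                                 wt_convention = NULL) {
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0))
  edges <- landscape_edges(landscape, wt_convention)
  rows <- lapply(thresholds, function(thr) {
    census <- enumerate_monotonic_paths(landscape, thr, wt_convention)
    data.frame(threshold = thr,
               n_edges_passing = census$n_edges_passing,
               n_paths_accessible = census$n_paths_accessible)
  })
  borderline <- lapply(thresholds, function(thr) {
    b <- edges[edges$ratio >= 0.8 * thr & edges$ratio <= 1.2 * thr, , drop = FALSE]
    rownames(b) <- NULL
    b
  })
  names(borderline) <- as.character(thresholds)
  out <- do.call(rbind, rows)
  structure(out, borderline = borderline,
            class = c("accessibility_report", "data.frame"))
}

#' @export
print.accessibility_report <- function(x, ...) {
  cat("Accessible-path census (strict > threshold):\n")
  print.data.frame(x, row.names = FALSE)
  b <- attr(x, "borderline")
  for (thr in names(b)) {
    cat(sprintf("\nEdges within 20%% of the %s-fold cutoff:\n", thr))
    if (nrow(b[[thr]]) == 0) cat("  (none)\n") else {
      d <- b[[thr]]
      d$from <- vapply(d$from, variant_name, character(1))
      d$to <- vapply(d$to, variant_name, character(1))
      print.data.frame(d, row.names = FALSE, digits = 3)
    }
  }
  invisible(x)
}
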