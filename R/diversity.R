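# Sliding-window nucleotide diversity (pi), GC content, and between-group
# delta-pi over whole-plastome alignments.
#
# pi is the mean number of pairwise differences per retained site:
#   pi = 2 / (n (n - 1)) * sum_{i<j} d_ij / L
# computed after complete deletion: every column containing anything other
# than A/C/G/T in any row (gaps, N, IUPAC ambiguity codes) is removed first.

#' Complete deletion of columns with missing data
#'
#' @param aln An alignment matrix (see [as_alignment()]) or a column slice of
#'   one.
#' @return The alignment restricted to columns where every row is one of
#'   A/C/G/T, column order preserved. May have zero columns.
#' @export
complete_deletion <- function(aln) {
  stopifnot(is.matrix(aln))
  keep <- colSums(matrix(aln %in% DNA_BASES, nrow = nrow(aln))) == nrow(aln)
  aln[, keep, drop = FALSE]
}

#' Nucleotide diversity of a retained alignment slice
#'
#' @param aln An alignment matrix whose columns have already passed
#'   [complete_deletion()] (pure A/C/G/T).
#' @return Mean pairwise differences per site (a value in `[0, 1]`), or
#'   `NA_real_` when zero columns remain (the no-data marker).
#' @export
nucleotide_diversity <- function(aln) {
  n <- nrow(aln)
  stopifnot(n >= 2L)
  L <- ncol(aln)
  if (L == 0L) return(NA_real_)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      total <- total + sum(aln[i, ] != aln[j, ])
    }
  }
  2 * total / (n * (n - 1)) / L
}

#' Sliding-window diversity and GC profile
#'
#' Windows start at alignment columns 0, `step`, `2 * step`, ... (0-based);
#' the final window may be truncated. Within each window, columns containing
#' any non-A/C/G/T character in the profiled rows are removed (complete
#' deletion), then pi and GC content are computed on the retained columns.
#' Windows retaining zero columns are reported with `pi = NA` and
#' `gc = NA` rather than dropped.
#'
#' @param aln An alignment matrix.
#' @param window Window size in alignment columns (default 600).
#' @param step Step size in alignment columns (default 200).
#' @param taxa Optional subset of row names to profile (default all rows).
#' @return A tibble of class `diversity_profile` with columns `window_start`
#'   (0-based column), `window_mid`, `pi`, `gc`, `n_retained_sites`,
#'   `n_taxa`. Attributes `window` and `step` record the grid.
#' @export
sliding_window_profile <- function(aln, window = 600L, step = 200L, taxa = NULL) {
  stopifnot(is.matrix(aln), window >= step, step >= 1L)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(aln))
    if (length(missing)) {
      abort(paste0("Taxa not in alignment: ", paste(missing, collapse = ", ")))
    }
    aln <- aln[taxa, , drop = FALSE]
  }
  if (nrow(aln) < 2L) {
    abort("Diversity profiling needs at least 2 sequences.")
  }
  L <- ncol(aln)
  starts <- seq(0L, max(0L, L - 1L), by = step)
  rows <- lapply(starts, function(s0) {
    e0 <- min(s0 + window, L)
    slice <- aln[, seq.int(s0 + 1L, e0), drop = FALSE]
    kept <- complete_deletion(slice)
    nr <- ncol(kept)
    if (nr == 0L) {
      pi <- NA_real_; gc <- NA_real_
    } else {
      pi <- nucleotide_diversity(kept)
      gc <- sum(kept %in% c("G", "C")) / length(kept)
    }
    tibble(window_start = s0, window_mid = (s0 + e0) / 2,
           pi = pi, gc = gc, n_retained_sites = nr, n_taxa = nrow(aln))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("diversity_profile", class(out))
  out
}

#' Per-group sliding-window profiles on a joint alignment
#'
#' @param aln An alignment matrix.
#' @param groups A data frame with columns `taxon` and `group` assigning each
#'   profiled row to a group (e.g. a genus).
#' @param window,step Window grid (see [sliding_window_profile()]).
#' @return A tibble: the row-bound per-group profiles with a leading `group`
#'   column.
#' @export
group_diversity_profiles <- function(aln, groups, window = 600L, step = 200L) {
  groups <- as_tibble(groups)
  if (!all(c("taxon", "group") %in% names(groups)) || nrow(groups) == 0L) {
    abort("`groups` must be a non-empty table with columns 'taxon' and 'group'.")
  }
  out <- lapply(split(groups$taxon, groups$group), function(tx) {
    if (length(tx) < 2L) {
      abort(sprintf("Group with fewer than 2 taxa: %s",
                    paste(tx, collapse = ", ")))
    }
    sliding_window_profile(aln, window = window, step = step, taxa = tx)
  })
  res <- dplyr::bind_rows(out, .id = "group")
  attr(res, "window") <- as.integer(window)
  attr(res, "step") <- as.integer(step)
  res
}

#' Delta diversity between two profiles on the same window grid
#'
#' @param a,b `diversity_profile` tibbles computed on the same alignment
#'   coordinate system and window configuration. The convention is
#'   `delta = pi_a - pi_b` (first-named group minus second).
#' @return A tibble with `window_start`, `window_mid`, `delta_pi`, restricted
#'   to windows where both profiles have data.
#' @export
delta_profile <- function(a, b) {
  same_grid <- identical(attr(a, "window"), attr(b, "window")) &&
    identical(attr(a, "step"), attr(b, "step")) &&
    identical(a$window_start, b$window_start)
  if (!same_grid) {
    abort("Coordinate error: profiles were not computed on the same window grid.")
  }
  out <- tibble(window_start = a$window_start, window_mid = a$window_mid,
                delta_pi = a$pi - b$pi)
  out[!is.na(out$delta_pi), , drop = FALSE]
}

#' Plot a diversity profile
#'
#' Draws per-window pi (solid) and GC content (dashed) against the window
#' midpoint, faceted by group when a `group` column is present.
#'
#' @param object A `diversity_profile` tibble (or grouped profile table).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diversity_profile <- function(object, ...) {
  df <- as_tibble(object)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_mid)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pi), colour = "firebrick", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gc * max(df$pi, na.rm = TRUE)),
                       colour = "steelblue", linetype = "dashed", na.rm = TRUE) +
    ggplot2::labs(x = "Alignment position (window midpoint)",
                  y = expression(pi),
                  caption = "dashed: GC content (rescaled)") +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) pl <- pl + ggplot2::facet_wrap(~group, ncol = 1)
  pl
}
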