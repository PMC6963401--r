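# Canonical orientation of an annotated plastome: rotate (and if needed
# reverse-complement) the circle so the order is LSC | IRb | SSC | IRa with
# the LSC starting at position 0, and remap all feature coordinates.
#
# Orientation convention (the choice between the two strands, both of which
# read LSC|IRb|SSC|IRa): the IR copy adjacent to the SSC end carrying ycf1 is
# IRa when a ycf1 annotation exists; otherwise the strand giving the
# lexicographically smaller LSC sequence is used.

#' Canonicalize the orientation of a plastome
#'
#' @param p A `plastome` object (see [read_plastome()]).
#' @param min_ir_length Minimum inverted-repeat length passed to
#'   [detect_inverted_repeats()].
#' @return A `plastome` with sequence rotated/complemented to canonical
#'   LSC|IRb|SSC|IRa order, feature coordinates remapped, and `regions`
#'   populated (tibble `region`, `start`, `end`, 0-based half-open).
#' @export
canonicalize_orientation <- function(p, min_ir_length = 1000L) {
  stopifnot(inherits(p, "plastome"))
  n <- nchar(p$sequence)
  det <- detect_inverted_repeats(p$sequence, min_ir_length = min_ir_length)

  lsc <- det[det$region == "LSC", ]
  ssc <- det[det$region == "SSC", ]
  ir1 <- det[det$region == "IR1", ]  # follows LSC on the forward strand
  ir2 <- det[det$region == "IR2", ]  # follows SSC on the forward strand

  # Forward reading: LSC, IR1, SSC, IR2  => IR1 = IRb, IR2 = IRa.
  # Reverse-complement reading: LSC', IR2', SSC', IR1' => IR2 = IRb, IR1 = IRa.
  # Decide which strand: ycf1 rule, else lexicographic LSC.
  use_reverse <- NULL
  ycf1 <- p$features[!is.na(p$features$name) & p$features$name == "ycf1", ]
  if (nrow(ycf1)) {
    mid <- (min(ycf1$start) + max(ycf1$end)) / 2
    # distance on circle from ycf1 midpoint to each SSC end
    ssc_end_fwd <- (ssc$start + ssc$length) %% n    # junction SSC/IR2
    ssc_end_rev <- ssc$start %% n                   # junction IR1/SSC
    d_fwd <- circ_dist(mid, ssc_end_fwd, n)
    d_rev <- circ_dist(mid, ssc_end_rev, n)
    # IRa must be the IR adjacent to the ycf1-bearing SSC end.
    # Forward strand makes IR2 (at SSC forward end) IRa.
    use_reverse <- d_rev < d_fwd
  }
  if (is.null(use_reverse)) {
    lsc_fwd <- circ_substr(p$sequence, lsc$start, lsc$length)
    lsc_rev <- revcomp(lsc_fwd)
    use_reverse <- lsc_rev < lsc_fwd
  }

  if (!use_reverse) {
    out <- rotate_plastome(p, lsc$start)
    region_lens <- c(lsc$length, ir1$length, ssc$length, ir2$length)
  } else {
    pr <- revcomp_plastome(p)
    # LSC start on the reverse-complemented coordinates
    lsc_end_fwd <- (lsc$start + lsc$length) %% n
    new_lsc_start <- (n - lsc_end_fwd) %% n
    out <- rotate_plastome(pr, new_lsc_start)
    region_lens <- c(lsc$length, ir2$length, ssc$length, ir1$length)
  }
  bounds <- as.integer(cumsum(c(0L, region_lens)))
  out$regions <- tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = bounds[1:4],
    end = bounds[2:5]
  )
  validate_canonical(out)
  out
}

circ_dist <- function(a, b, n) {
  d <- abs(((a - b) %% n + n) %% n)
  min(d, n - d)
}

# rotate the circle so 0-based position `at` becomes 0; features remapped,
# features crossing the new origin are split into two parts
rotate_plastome <- function(p, at) {
  n <- nchar(p$sequence)
  at <- ((at %% n) + n) %% n
  if (at == 0L) return(p)
  seq2 <- rotate_string(p$sequence, at)
  f <- p$features
  if (nrow(f)) {
    rows <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      s <- (f$start[i] - at) %% n
      e <- s + (f$end[i] - f$start[i])
      if (e <= n) {
        rows[[i]] <- tibble(fid = f$fid[i], name = f$name[i], kind = f$kind[i],
                            start = as.integer(s), end = as.integer(e),
                            strand = f$strand[i], part = f$part[i])
      } else {
        rows[[i]] <- tibble(fid = f$fid[i], name = f$name[i], kind = f$kind[i],
                            start = c(as.integer(s), 0L),
                            end = c(n, as.integer(e - n)),
                            strand = f$strand[i], part = f$part[i])
      }
    }
    f <- dplyr::bind_rows(rows)
    f <- renumber_parts(f)
  }
  new_plastome(p$taxon_id, seq2, f, regions = NULL)
}

# reverse-complement the whole circle; feature [s, e) -> [n - e, n - s),
# strands flip, part order reversed so parts stay position-ordered
revcomp_plastome <- function(p) {
  n <- nchar(p$sequence)
  f <- p$features
  if (nrow(f)) {
    f <- dplyr::mutate(f,
      new_start = n - .data$end,
      new_end = n - .data$start,
      strand = ifelse(.data$strand == "+", "-", "+"))
    f$start <- as.integer(f$new_start)
    f$end <- as.integer(f$new_end)
    f$new_start <- NULL; f$new_end <- NULL
    f <- renumber_parts(f)
  }
  new_plastome(p$taxon_id, revcomp(p$sequence), f, regions = NULL)
}

renumber_parts <- function(f) {
  f <- f[order(f$fid, f$start), , drop = FALSE]
  # merge book-keeping splits (an origin-crossing feature cut by rotation)
  # back into single intervals once they become contiguous
  keep <- rep(TRUE, nrow(f))
  if (nrow(f) >= 2L) {
    for (i in seq.int(2L, nrow(f))) {
      if (f$fid[i] == f$fid[i - 1L] && f$start[i] == f$end[i - 1L]) {
        f$end[i - 1L] <- f$end[i]
        f$start[i] <- f$start[i - 1L]
        keep[i - 1L] <- FALSE
      }
    }
  }
  f <- f[keep, , drop = FALSE]
  f <- dplyr::group_by(f, .data$fid)
  f <- dplyr::mutate(f, part = dplyr::row_number())
  dplyr::ungroup(f)
}

validate_canonical <- function(p) {
  r <- p$regions
  n <- nchar(p$sequence)
  stopifnot(identical(r$region, c("LSC", "IRb", "SSC", "IRa")),
            r$start[1] == 0L, r$end[4] == n,
            all(r$start[-1] == r$end[-4]))
  irb <- substr(p$sequence, r$start[2] + 1L, r$end[2])
  ira <- substr(p$sequence, r$start[3 + 1] + 1L, r$end[4])
  if (!identical(revcomp(irb), ira)) {
    abort("Internal error: canonical IRb is not the exact reverse complement of IRa.")
  }
  invisible(p)
}
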