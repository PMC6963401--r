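# Inverted-repeat detection on a circular sequence: seed-and-extend exact
# matching. The canonical plastome carries two large, exactly
# reverse-complementary repeats; detection returns the longest disjoint
# exactly reverse-complementary pair plus the two single-copy intervals.

#' Detect the quadripartite structure of a circular sequence
#'
#' Finds the longest pair of disjoint, exactly reverse-complementary segments
#' on the circle (the inverted repeats) and labels the shorter single-copy
#' interval between them SSC and the longer one LSC. Seeds of
#' `min_ir_length / 2` are matched against the reverse complement and extended
#' to maximal exact matches; a mismatch-tolerant extension beyond the exact
#' core is reported as an attribute and via a message, never merged into the
#' coordinates.
#'
#' @param sequence Circular DNA string (uppercase A/C/G/T/N).
#' @param min_ir_length Minimum repeat length to accept (bp).
#' @return A tibble with columns `region` (`LSC`, `IR1`, `SSC`, `IR2` in
#'   circular order starting at the LSC), `start` (0-based position on the
#'   input circle) and `length`. Attribute `mismatch_extension` carries the
#'   lengths by which each IR flank could be extended when allowing isolated
#'   mismatches.
#' @export
detect_inverted_repeats <- function(sequence, min_ir_length = 1000L) {
  n <- nchar(sequence)
  if (n < 4L * min_ir_length) {
    abort(sprintf(
      "Structure error: sequence (%d bp) shorter than 4 x min_ir_length (%d bp).",
      n, 4L * min_ir_length))
  }
  chars <- strsplit(sequence, "")[[1]]
  seedlen <- max(50L, as.integer(min_ir_length %/% 2L))
  rc <- revcomp(sequence)
  rc_doubled <- Biostrings::DNAString(paste0(rc, rc))

  # candidate maximal reverse-complement matches, deduplicated by identity
  cands <- list()
  seen <- character()
  seed_starts <- seq(0L, n - 1L, by = seedlen)
  for (s0 in seed_starts) {
    seed <- circ_substr(sequence, s0, seedlen)
    if (grepl("N", seed, fixed = TRUE)) next
    hits <- Biostrings::matchPattern(seed, rc_doubled)
    if (length(hits) == 0L) next
    for (h in BiocGenerics::start(hits)) {
      if (h > n) next  # duplicate of a first-copy hit
      j <- h - 1L                      # 0-based start in rc
      b_end <- n - j                   # seed == revcomp(S[b_start, b_end))
      b_start <- b_end - seedlen
      ext <- extend_rc_match(chars, s0, b_start, seedlen, n)
      if (ext$len < min_ir_length) next
      key <- paste(ext$a_start %% n, ext$b_start %% n, ext$len)
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1L]] <- ext
    }
  }
  if (!length(cands)) {
    abort(sprintf("Structure error: no inverted repeat of >= %d bp found.",
                  min_ir_length))
  }
  # keep disjoint pairs only; the two arms of one candidate are (a, b)
  ok <- vapply(cands, function(e) {
    disjoint_on_circle(e$a_start, e$len, e$b_start, e$len, n)
  }, logical(1))
  cands <- cands[ok]
  # drop palindromic self-overlaps and keep the longest; one candidate pair
  # describes both arms, so dedupe arm-order swaps
  if (!length(cands)) {
    abort(sprintf("Structure error: no disjoint inverted-repeat pair of >= %d bp found.",
                  min_ir_length))
  }
  lens <- vapply(cands, function(e) e$len, integer(1))
  best_len <- max(lens)
  best <- cands[lens == best_len]
  keys <- vapply(best, function(e) {
    arms <- sort(c(e$a_start %% n, e$b_start %% n))
    paste(arms, collapse = ":")
  }, character(1))
  best <- best[!duplicated(keys)]
  if (length(best) > 1L) {
    desc <- vapply(best, function(e) {
      sprintf("[%d+%d / %d+%d]", e$a_start %% n, e$len, e$b_start %% n, e$len)
    }, character(1))
    abort(paste0("Ambiguity error: multiple non-overlapping inverted-repeat ",
                 "candidates of equal length ", best_len, " bp: ",
                 paste(desc, collapse = ", ")))
  }
  e <- best[[1]]
  if (2L * e$len >= n) {
    abort("Degenerate-structure error: inverted repeats cover the whole circle.")
  }

  a0 <- e$a_start %% n
  b0 <- e$b_start %% n
  # single-copy intervals between the two arms, on the circle
  gap1_start <- (a0 + e$len) %% n
  gap1_len <- (b0 - gap1_start) %% n
  gap2_start <- (b0 + e$len) %% n
  gap2_len <- (a0 - gap2_start) %% n
  if (gap1_len == 0L || gap2_len == 0L) {
    abort("Degenerate-structure error: inverted repeats are adjacent; no single-copy regions.")
  }
  if (gap1_len >= gap2_len) {
    lsc <- c(gap1_start, gap1_len); ssc <- c(gap2_start, gap2_len)
    ir_after_lsc <- b0; ir_after_ssc <- a0
  } else {
    lsc <- c(gap2_start, gap2_len); ssc <- c(gap1_start, gap1_len)
    ir_after_lsc <- a0; ir_after_ssc <- b0
  }
  out <- tibble(
    region = c("LSC", "IR1", "SSC", "IR2"),
    start = c(lsc[1], ir_after_lsc, ssc[1], ir_after_ssc),
    length = c(lsc[2], e$len, ssc[2], e$len)
  )
  mm <- mismatch_extension(chars, e, n)
  if (any(mm > 0L)) {
    inform(sprintf(
      "Inverted-repeat arms extend %d bp (left) / %d bp (right) beyond the exact core when tolerating mismatches.",
      mm[1], mm[2]))
  }
  attr(out, "mismatch_extension") <- mm
  out
}

# Extend an exact reverse-complement match maximally on the circle.
# Invariant maintained: S[a, a+len) == revcomp(S[b, b+len)).
# Extending a to the left pairs with extending b to the right, and vice versa.
extend_rc_match <- function(chars, a_start, b_start, len, n) {
  at <- function(i) chars[(i %% n) + 1L]
  # grow left of a / right of b
  total <- 2L * len
  while (total < n) {
    ai <- a_start - 1L
    bj <- b_start + len
    if (at(ai) != complement_chars(at(bj))) break
    if (!disjoint_on_circle(ai, 1L, bj, 1L, n)) break
    a_start <- a_start - 1L
    len <- len + 1L
    total <- total + 2L
    if (!disjoint_on_circle(a_start, len, b_start, len, n)) {
      a_start <- a_start + 1L; len <- len - 1L; break
    }
  }
  # grow right of a / left of b
  while (2L * len < n) {
    ai <- a_start + len
    bj <- b_start - 1L
    if (at(ai) != complement_chars(at(bj))) break
    cand_b <- b_start - 1L
    if (!disjoint_on_circle(a_start, len + 1L, cand_b, len + 1L, n)) break
    b_start <- cand_b
    len <- len + 1L
  }
  list(a_start = a_start, b_start = b_start, len = len)
}

# how far each flank could extend when single mismatches are tolerated
# (requires 10 subsequent matches after each tolerated mismatch)
mismatch_extension <- function(chars, e, n) {
  at <- function(i) chars[(i %% n) + 1L]
  probe <- function(a_next, b_next, dir_a, dir_b) {
    ext <- 0L
    budget_guard <- 0L
    while (ext < n %/% 4L) {
      if (at(a_next) == complement_chars(at(b_next))) {
        ext <- ext + 1L
      } else {
        # tolerate if the next 10 positions match
        ok <- TRUE
        for (k in 1:10) {
          if (at(a_next + dir_a * k) != complement_chars(at(b_next + dir_b * k))) {
            ok <- FALSE; break
          }
        }
        if (!ok) break
        ext <- ext + 1L
      }
      a_next <- a_next + dir_a
      b_next <- b_next + dir_b
      budget_guard <- budget_guard + 1L
      if (budget_guard > n) break
    }
    ext
  }
  left <- probe(e$a_start - 1L, e$b_start + e$len, -1L, +1L)
  right <- probe(e$a_start + e$len, e$b_start - 1L, +1L, -1L)
  c(left = left, right = right)
}

# are the circular intervals [s1, s1+l1) and [s2, s2+l2) disjoint?
disjoint_on_circle <- function(s1, l1, s2, l2, n) {
  s1 <- ((s1 %% n) + n) %% n
  s2 <- ((s2 %% n) + n) %% n
  iv <- function(s, l) {
    if (s + l <= n) list(c(s, s + l)) else list(c(s, n), c(0, s + l - n))
  }
  for (x in iv(s1, l1)) for (y in iv(s2, l2)) {
    if (x[1] < y[2] && y[1] < x[2]) return(FALSE)
  }
  TRUE
}
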