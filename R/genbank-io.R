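# Minimal GenBank flat-file reader/writer for annotated plastomes.
# Only the fields the pipeline consumes are handled: LOCUS name, the FEATURES
# table (gene/CDS/tRNA/rRNA with /gene qualifiers, join()/complement()
# locations, partial markers '<'/'>') and the ORIGIN sequence.

#' Read an annotated plastome from GenBank flat-file text
#'
#' Parses a single GenBank entry into an annotated-plastome object holding the
#' (circular) sequence and a feature table. Coordinates are converted to
#' 0-based half-open on input. Quadripartite region assignments are left unset
#' until [canonicalize_orientation()] is called.
#'
#' @param x Path to a GenBank file, or a character vector of GenBank lines.
#' @return An object of class `plastome`: a list with `taxon_id` (string),
#'   `sequence` (uppercase string), `features` (tibble with columns `fid` (feature
#'   instance id, distinguishing the two IR copies of a gene), `name`,
#'   `kind`, `start`, `end`, `strand`, `part`) and `regions` (tibble or
#'   `NULL`).
#' @export
read_plastome <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L) {
    abort(sprintf("Malformed GenBank record: expected one LOCUS line, found %d.",
                  length(locus_i)))
  }
  taxon_id <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[locus_i])), "\\s+")[[1]][1]

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1L) {
    abort("Malformed GenBank record: no ORIGIN section (input error: empty sequence).")
  }
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L

  # --- sequence ---
  seq_lines <- if (end_i - origin_i > 1L) {
    lines[seq(origin_i + 1L, end_i - 1L)]
  } else {
    character(0)
  }
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) {
    abort("Input error: GenBank record has an empty sequence.")
  }

  # --- features ---
  features <- empty_features()
  if (length(feat_i) == 1L && feat_i < origin_i) {
    flines <- lines[seq(feat_i + 1L, origin_i - 1L)]
    features <- parse_feature_table(flines)
  }

  new_plastome(taxon_id, sequence, features, regions = NULL)
}

empty_features <- function() {
  tibble(fid = integer(), name = character(), kind = character(),
         start = integer(), end = integer(), strand = character(),
         part = integer())
}

parse_feature_table <- function(flines) {
  # a new feature starts at indentation 5 with a key; qualifiers at indent 21
  is_key <- grepl("^ {5}\\S", flines)
  idx <- which(is_key)
  keep_kinds <- c("gene", "CDS", "tRNA", "rRNA", "intron", "pseudogene")
  rows <- list()
  for (k in seq_along(idx)) {
    i0 <- idx[k]
    i1 <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
    block <- flines[i0:i1]
    key <- sub("^ {5}(\\S+).*", "\\1", block[1])
    if (!key %in% keep_kinds) next
    # location may continue over lines until the first qualifier line
    qual_start <- grep("^ {21}/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
    loc <- paste(trimws(sub("^ {5}\\S+\\s*", "", block[1])),
                 paste(trimws(block[seq_len(loc_end)[-1]]), collapse = ""),
                 sep = "")
    loc <- gsub("\\s", "", loc)
    parsed <- tryCatch(parse_location(loc),
                       error = function(e) {
                         abort(sprintf("Malformed GenBank record at line '%s': %s",
                                       trimws(block[1]), conditionMessage(e)))
                       })
    quals <- paste(block[seq.int(loc_end + 1L, length.out = max(0L, length(block) - loc_end))],
                   collapse = " ")
    gene <- if (grepl("/gene=\"", quals)) {
      sub('.*?/gene="([^"]+)".*', "\\1", quals)
    } else if (grepl("/label=\"", quals)) {
      sub('.*?/label="([^"]+)".*', "\\1", quals)
    } else {
      NA_character_
    }
    pseudo <- grepl("/pseudo\\b", quals)
    kind <- if (pseudo && key == "gene") "pseudogene" else key
    rows[[length(rows) + 1L]] <- tibble(
      fid = length(rows) + 1L, name = gene, kind = kind,
      start = parsed$start, end = parsed$end,
      strand = parsed$strand, part = seq_along(parsed$start)
    )
  }
  if (!length(rows)) return(empty_features())
  out <- dplyr::bind_rows(rows)
  out$name[is.na(out$name)] <- paste0("feature", cumsum(is.na(out$name))[is.na(out$name)])
  out
}

# Parse a GenBank location string into 0-based half-open intervals.
parse_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    # complement may also wrap inner joins; handled above only at top level
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  starts <- integer(length(parts)); ends <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- gsub("[<>]", "", parts[i])
    inner_strand <- NULL
    if (grepl("^complement\\(", p)) {
      inner_strand <- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (!grepl("^\\d+\\.\\.\\d+$", p) && !grepl("^\\d+$", p)) {
      stop(sprintf("cannot parse location part '%s'", parts[i]))
    }
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      se <- c(as.integer(p), as.integer(p))
    }
    starts[i] <- se[1] - 1L   # 1-based inclusive -> 0-based half-open
    ends[i] <- se[2]
    if (!is.null(inner_strand)) strand <- inner_strand
  }
  ord <- order(starts)
  list(start = starts[ord], end = ends[ord], strand = strand)
}

#' Construct an annotated-plastome object
#'
#' @param taxon_id Taxon identifier.
#' @param sequence Uppercase DNA string (circular).
#' @param features Feature tibble (`fid`, `name`, `kind`, `start`, `end`,
#'   `strand`, `part`), 0-based half-open coordinates.
#' @param regions Optional quadripartite region tibble (`region`, `start`,
#'   `end`) with `region` in `LSC`, `IRb`, `SSC`, `IRa`.
#' @return A `plastome` object.
#' @export
new_plastome <- function(taxon_id, sequence, features = empty_features(),
                         regions = NULL) {
  stopifnot(is.character(taxon_id), nchar(sequence) > 0L)
  structure(list(taxon_id = taxon_id,
                 sequence = toupper(sequence),
                 features = features,
                 regions = regions),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp, %d feature rows%s\n",
              x$taxon_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$features),
              if (is.null(x$regions)) " (orientation not canonicalized)"
              else " (canonical LSC|IRb|SSC|IRa)"))
  if (!is.null(x$regions)) print(x$regions)
  invisible(x)
}

#' Write an annotated plastome as a GenBank flat file
#'
#' @param p A `plastome` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nchar(p$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     p$taxon_id, n), con)
  writeLines(sprintf("DEFINITION  %s plastome, synthetic.", p$taxon_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  if (nrow(p$features)) {
    feats <- split(p$features, p$features$fid)
    # preserve genomic order
    ord <- order(vapply(feats, function(f) min(f$start), integer(1)))
    for (f in feats[ord]) {
      f <- f[order(f$part), , drop = FALSE]
      ivs <- sprintf("%d..%d", f$start + 1L, f$end)
      loc <- if (length(ivs) > 1L) sprintf("join(%s)", paste(ivs, collapse = ",")) else ivs
      if (f$strand[1] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", f$kind[1], loc), con)
      writeLines(sprintf("                     /gene=\"%s\"", f$name[1]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(p$sequence)
  pos <- seq(1L, n, by = 60L)
  for (p0 in pos) {
    chunk <- substr(s, p0, min(p0 + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p0, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
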