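#' Binary cognate presence/absence matrices
#'
#' A `cognate_matrix` holds one row per language variety and one 0/1 column
#' per cognate set, with `NA` marking meanings that were not scored for a
#' variety (written as `?` in NEXUS). Each column is tagged with the basic-
#' vocabulary meaning it encodes; several columns usually share a meaning,
#' one per cognate class attested for that meaning.
#'
#' @param states integer/numeric matrix of 0/1 (NA = missing) with rownames
#'   giving the variety labels.
#' @param meaning_class character vector, one meaning identifier per column.
#'   Defaults to one distinct meaning per column.
#' @param provenance free-text source tag.
#'
#' @return An object of class `cognate_matrix`: a list with elements
#'   `taxa`, `states` (taxa x K matrix), `meaning_class`, `provenance`.
#' @export
#' @examples
#' m <- cognate_matrix(rbind(A = c(1, 0), B = c(1, 1)),
#'                     meaning_class = c("dog", "dog"))
#' m
cognate_matrix <- function(states, meaning_class = NULL, provenance = "") {
  states <- as.matrix(states)
  if (is.null(rownames(states))) stop("`states` must have rownames (taxon labels)")
  storage.mode(states) <- "integer"
  taxa <- rownames(states)
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  bad <- !(states %in% c(0L, 1L, NA))
  if (any(bad)) stop("cognate states must be 0, 1 or NA")
  if (ncol(states) < 1) stop("need at least one cognate column")
  pres <- colSums(states == 1L, na.rm = TRUE)
  if (any(pres == 0)) {
    stop("column(s) ", paste(which(pres == 0), collapse = ", "),
         " have no presence: unobservable under ascertainment")
  }
  if (is.null(meaning_class)) {
    meaning_class <- colnames(states) %||% sprintf("m%03d", seq_len(ncol(states)))
  }
  if (length(meaning_class) != ncol(states)) {
    stop("meaning_class must have one entry per column")
  }
  structure(
    list(taxa = taxa, states = states,
         meaning_class = as.character(meaning_class),
         provenance = provenance),
    class = "cognate_matrix")
}

#' @export
print.cognate_matrix <- function(x, ...) {
  cat(sprintf("<cognate_matrix> %d taxa x %d cognate columns (%d meanings)\n",
              length(x$taxa), ncol(x$states),
              length(unique(x$meaning_class))))
  miss <- mean(is.na(x$states))
  cat(sprintf("  missing entries: %.1f%%", 100 * miss))
  if (nzchar(x$provenance)) cat("  source:", x$provenance)
  cat("\n")
  invisible(x)
}

#' @export
dim.cognate_matrix <- function(x) dim(x$states)

#' Read a binary character matrix from a NEXUS file
#'
#' Parses a DATA or CHARACTERS block with `symbols="01"` and `?` as the
#' missing mark. Both sequential and interleaved matrices are accepted;
#' taxa keep their file order. A `charset`-style comment of the form
#' `[meaning: <id>]` immediately preceding the MATRIX keyword column list is
#' not required; if a `CHARSTATELABELS` line or a `[meanings ...]` comment is
#' present, column meaning tags are taken from it, otherwise every column is
#' its own meaning (see [cognate_similarity()] for why meanings matter).
#'
#' @param path path to a NEXUS file.
#' @return A [cognate_matrix()].
#' @export
read_nexus_binary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", raw)
  up <- toupper(lines)
  if (!any(grepl("#NEXUS", up[1:min(5, length(up))], fixed = TRUE))) {
    stop("parse error at line 1: missing #NEXUS header")
  }
  begin <- grep("BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (!length(begin)) stop("parse error: no DATA/CHARACTERS block found")
  b <- begin[1]
  endl <- grep("^\\s*END\\s*;", up)
  endl <- endl[endl > b]
  if (!length(endl)) stop("parse error at line ", b, ": unterminated block")
  e <- endl[1]
  block <- lines[b:e]
  bup <- up[b:e]

  nchar_m <- regmatches(bup, regexpr("NCHAR\\s*=\\s*[0-9]+", bup))
  ntax_m <- regmatches(bup, regexpr("NTAX\\s*=\\s*[0-9]+", bup))
  nchar_n <- if (length(nchar_m)) as.integer(sub(".*=\\s*", "", nchar_m[1])) else NA
  ntax_n <- if (length(ntax_m)) as.integer(sub(".*=\\s*", "", ntax_m[1])) else NA
  fmt <- grep("FORMAT", bup)
  if (length(fmt)) {
    fline <- bup[fmt[1]]
    sym <- regmatches(fline, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', fline))
    if (length(sym)) {
      symbols <- gsub('.*"([^"]*)".*', "\\1", sym)
      symbols <- gsub("\\s", "", symbols)
      if (!all(strsplit(symbols, "")[[1]] %in% c("0", "1"))) {
        stop("data error at line ", b + fmt[1] - 1,
             ": non-binary symbols \"", symbols, "\"")
      }
    }
  }

  # optional meaning tags: a comment line "[meanings m1 m1 m2 ...]"
  meanings <- NULL
  mg <- grep("^\\s*\\[\\s*meanings\\b", block, ignore.case = TRUE)
  if (length(mg)) {
    toks <- strsplit(gsub("[][]", "", block[mg[1]]), "\\s+")[[1]]
    meanings <- toks[toks != "" & toupper(toks) != "MEANINGS"]
  }

  mstart <- grep("^\\s*MATRIX\\b", bup)
  if (!length(mstart)) stop("parse error at line ", b, ": no MATRIX keyword")
  rows <- list()
  order_seen <- character()
  i <- mstart[1] + 1
  while (i <= length(block)) {
    ln <- block[i]
    lnum <- b + i - 1
    if (grepl("^\\s*;", ln)) break
    ln2 <- gsub("\\[[^]]*\\]", "", ln)  # strip comments
    if (grepl("^\\s*$", ln2)) { i <- i + 1; next }
    m <- regmatches(ln2, regexec("^\\s*('[^']+'|\"[^\"]+\"|\\S+)\\s+(.*)$", ln2))[[1]]
    if (length(m) < 3) stop("parse error at line ", lnum, ": malformed matrix row")
    tax <- gsub("^['\"]|['\"]$", "", m[2])
    seqs <- gsub("\\s", "", m[3])
    if (grepl(";", seqs)) seqs <- sub(";.*$", "", seqs)
    chars <- strsplit(seqs, "")[[1]]
    bad <- setdiff(unique(chars), c("0", "1", "?", "-"))
    if (length(bad)) {
      stop("data error at line ", lnum, ": non-binary symbol '",
           bad[1], "' for taxon ", tax)
    }
    if (!tax %in% order_seen) order_seen <- c(order_seen, tax)
    rows[[tax]] <- c(rows[[tax]], chars)
    i <- i + 1
  }
  if (!length(rows)) stop("parse error: empty MATRIX")
  lens <- vapply(rows, length, 1L)
  if (length(unique(lens)) != 1) {
    stop("parse error: unequal row lengths (",
         paste(unique(lens), collapse = ", "), ")")
  }
  if (!is.na(nchar_n) && lens[1] != nchar_n) {
    stop("parse error: NCHAR=", nchar_n, " but rows have ", lens[1], " characters")
  }
  if (!is.na(ntax_n) && length(rows) != ntax_n) {
    stop("parse error: NTAX=", ntax_n, " but ", length(rows), " taxa found")
  }
  st <- do.call(rbind, lapply(rows[order_seen], function(ch) {
    out <- suppressWarnings(as.integer(ch))
    out[ch %in% c("?", "-")] <- NA_integer_
    out
  }))
  rownames(st) <- order_seen
  cognate_matrix(st, meaning_class = meanings, provenance = path)
}

#' Write a cognate matrix as NEXUS
#'
#' Writes a DATA block (`symbols="01"`, `missing=?`) that
#' [read_nexus_binary()] reads back losslessly, including the meaning tags
#' (as a `[meanings ...]` comment line).
#'
#' @param m a [cognate_matrix()].
#' @param path output file path (UTF-8).
#' @return `path`, invisibly.
#' @export
write_nexus_binary <- function(m, path) {
  st <- m$states
  ch <- matrix(as.character(st), nrow = nrow(st))
  ch[is.na(st)] <- "?"
  seqs <- apply(ch, 1, paste0, collapse = "")
  lab <- m$taxa
  needs_quote <- grepl("[^A-Za-z0-9_.]", lab)
  lab[needs_quote] <- paste0("'", lab[needs_quote], "'")
  wid <- max(nchar(lab)) + 2
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
    sprintf("  [meanings %s]", paste(m$meaning_class, collapse = " ")),
    "  MATRIX"), con)
  writeLines(sprintf("    %-*s%s", wid, lab, seqs), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Encode per-meaning cognate-class assignments as a binary matrix
#'
#' Turns cognate judgments (for each meaning, a partition of the varieties
#' into cognate classes, with "no data" allowed) into the presence/absence
#' matrix the likelihood works on: one column per (meaning, class) pair.
#' Varieties unscored for a meaning get `?` in all of that meaning's columns.
#'
#' @param assignments named list; one element per meaning, itself a named
#'   character vector mapping taxon -> class label, with `NA` for "no data".
#'   Taxa absent from a meaning's vector are treated as "no data".
#' @param taxa character vector fixing row order; defaults to the union of
#'   taxa seen across meanings, in first-appearance order.
#' @return A [cognate_matrix()].
#' @export
#' @examples
#' enc <- encode_cognate_sets(list(
#'   dog = c(A = "I", B = "I", C = "II"),
#'   eye = c(A = "I", B = "II", C = NA)))
#' enc$states
encode_cognate_sets <- function(assignments, taxa = NULL) {
  if (!length(assignments) || is.null(names(assignments))) {
    stop("`assignments` must be a named list of per-meaning class vectors")
  }
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(assignments, names)))
  }
  cols <- list(); tags <- character()
  for (mn in names(assignments)) {
    a <- assignments[[mn]]
    if (is.null(names(a))) stop("meaning '", mn, "': class vector must be named by taxon")
    a <- a[!is.na(a)]
    classes <- unique(a)
    if (!length(classes)) next  # meaning with no data contributes no column
    for (cl in classes) {
      members <- names(a)[a == cl]
      if (!length(members)) stop("meaning '", mn, "': empty class '", cl, "'")
      col <- rep(NA_integer_, length(taxa))
      names(col) <- taxa
      scored <- intersect(taxa, names(assignments[[mn]])[!is.na(assignments[[mn]])])
      col[scored] <- 0L
      col[intersect(members, taxa)] <- 1L
      cols[[length(cols) + 1L]] <- col
      tags <- c(tags, mn)
    }
  }
  st <- do.call(cbind, cols)
  rownames(st) <- taxa
  colnames(st) <- make.unique(tags, sep = "_c")
  cognate_matrix(st, meaning_class = tags)
}

#' Pairwise lexical similarity and distance
#'
#' For every pair of varieties, the similarity is the fraction of meanings --
#' among those scored in both -- for which the two share at least one cognate
#' class; the distance is its complement. This is the quantity behind the
#' Swadesh 90% basic-vocabulary criterion, so it counts *meanings*, not raw
#' columns (set `per = "column"` for the per-column variant).
#'
#' @param m a [cognate_matrix()].
#' @param per count sharing per `"meaning"` (default) or per `"column"`.
#' @return A list of class `lexical_distance` with symmetric matrices
#'   `similarity` and `distance` (zero diagonal), a logical matrix
#'   `defined` flagging pairs with at least one jointly scored meaning, and
#'   the taxa. Undefined pairs hold `NA`, never a silent 0.
#' @export
cognate_similarity <- function(m, per = c("meaning", "column")) {
  per <- match.arg(per)
  stopifnot(inherits(m, "cognate_matrix"))
  n <- length(m$taxa)
  if (n < 2) stop("need at least 2 taxa")
  st <- m$states
  groups <- if (per == "meaning") m$meaning_class else as.character(seq_len(ncol(st)))
  gidx <- split(seq_len(ncol(st)), groups)
  s <- matrix(NA_real_, n, n, dimnames = list(m$taxa, m$taxa))
  defined <- matrix(FALSE, n, n, dimnames = list(m$taxa, m$taxa))
  diag(s) <- 1; diag(defined) <- TRUE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- 0L; scored <- 0L
    for (g in gidx) {
      xi <- st[i, g]; xj <- st[j, g]
      if (all(is.na(xi)) || all(is.na(xj))) next
      scored <- scored + 1L
      if (any(xi == 1L & xj == 1L, na.rm = TRUE)) shared <- shared + 1L
    }
    if (scored > 0) {
      s[i, j] <- s[j, i] <- shared / scored
      defined[i, j] <- defined[j, i] <- TRUE
    }
  }
  d <- 1 - s
  diag(d) <- 0
  structure(list(taxa = m$taxa, similarity = s, distance = d, defined = defined),
            class = "lexical_distance")
}

#' @export
print.lexical_distance <- function(x, ...) {
  cat(sprintf("<lexical_distance> %d taxa; mean similarity %.3f\n",
              length(x$taxa),
              mean(x$similarity[upper.tri(x$similarity)], na.rm = TRUE)))
  if (any(!x$defined)) cat("  note: some pairs share no scored meaning (NA)\n")
  invisible(x)
}

#' Read tip coordinates
#'
#' Three-column tab-delimited text: taxon, latitude, longitude (decimal
#' degrees, WGS84). A header line is detected and skipped.
#'
#' @param path file path.
#' @return A tibble with columns `taxon`, `lat`, `lon`.
#' @export
read_taxon_geo <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("[A-Za-z]", strsplit(first, "\t")[[1]][2] %||% "x")
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("taxon", "lat", "lon")
  validate_taxon_geo(df)
  tibble::as_tibble(df[, c("taxon", "lat", "lon")])
}

#' @rdname read_taxon_geo
#' @param geo a data frame with columns `taxon`, `lat`, `lon`.
#' @export
write_taxon_geo <- function(geo, path) {
  validate_taxon_geo(geo)
  utils::write.table(geo[, c("taxon", "lat", "lon")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_taxon_geo <- function(geo) {
  stopifnot(all(c("taxon", "lat", "lon") %in% names(geo)))
  if (anyDuplicated(geo$taxon)) stop("duplicate taxon in coordinates")
  if (any(geo$lat < -90 | geo$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(geo$lon < -180 | geo$lon > 180)) stop("longitude outside [-180, 180]")
  invisible(geo)
}
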