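#' Construct a discrete morphological character matrix
#'
#' Entries are *state sets* encoded as integer bitmasks over the symbol
#' alphabet `0 ... nstates-1`: a singleton set is an observed score, a
#' multi-element set a polymorphism, and the full set a missing entry
#' (`?` or gap).  Characters are equally weighted and unordered unless
#' stated otherwise.
#'
#' @param states either an n x c integer bitmask matrix, or an n x c
#'   character matrix with entries like `"0"`, `"?"`, `"-"`, `"01"`
#'   (polymorphism as the concatenated states).
#' @param taxa n taxon labels (defaults to rownames).
#' @param nstates alphabet size (default 10, symbols `0`-`9`).
#' @param weights per-character positive weights (default 1).
#' @param ordered per-character additive flag (default `FALSE`; only
#'   unordered Fitch scoring is implemented, the flag is carried for
#'   matrix compatibility and must currently be all `FALSE`).
#' @param orig_index original 1-based character indices (tracks
#'   exclusions).
#' @return An object of class `char_matrix`.
#' @export
character_matrix <- function(states, taxa = rownames(states), nstates = 10L,
                             weights = NULL, ordered = NULL,
                             orig_index = NULL) {
  if (is.character(states)) {
    chr <- as.matrix(states)
    mask <- matrix(0L, nrow(chr), ncol(chr))
    full <- bitwShiftL(1L, nstates) - 1L
    for (i in seq_len(nrow(chr))) {
      for (j in seq_len(ncol(chr))) {
        mask[i, j] <- .symbols_to_mask(chr[i, j], nstates)
      }
    }
  } else {
    mask <- as.matrix(states)
    storage.mode(mask) <- "integer"
  }
  n <- nrow(mask); c <- ncol(mask)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  if (is.null(weights)) weights <- rep(1, c)
  if (is.null(ordered)) ordered <- rep(FALSE, c)
  if (is.null(orig_index)) orig_index <- seq_len(c)
  full <- bitwShiftL(1L, as.integer(nstates)) - 1L
  if (any(mask <= 0L) || any(mask > full))
    stop("invalid state set encountered (empty or outside alphabet)",
         call. = FALSE)
  if (any(apply(mask, 1, function(r) all(r == full))))
    stop("every taxon needs at least one non-missing entry", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  dimnames(mask) <- list(taxa, NULL)
  structure(list(taxa = as.character(taxa), mask = mask,
                 nstates = as.integer(nstates), weights = as.numeric(weights),
                 ordered = as.logical(ordered),
                 orig_index = as.integer(orig_index)),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix: %d taxa x %d characters (alphabet 0-%d)>\n",
              length(x$taxa), ncol(x$mask), x$nstates - 1L))
  invisible(x)
}

#' Number of taxa / characters of a character matrix
#' @param M a [character_matrix()].
#' @return Integer.
#' @export
n_taxa <- function(M) length(M$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(M) ncol(M$mask)

.symbols_to_mask <- function(tok, nstates) {
  full <- bitwShiftL(1L, as.integer(nstates)) - 1L
  tok <- gsub("[(){} ]", "", tok)
  if (tok %in% c("?", "-", "")) return(full)
  digs <- strsplit(tok, "")[[1]]
  if (any(digs %in% c("?", "-"))) return(full)
  v <- suppressWarnings(as.integer(digs))
  if (any(is.na(v)) || any(v >= nstates))
    stop(sprintf("unknown state symbol in '%s'", tok), call. = FALSE)
  as.integer(sum(bitwShiftL(1L, unique(v))))
}

#' Drop characters by their original 1-based indices
#'
#' @param M a [character_matrix()].
#' @param exclude integer vector of original character indices to drop
#'   (e.g. a published exclusion such as character 264).
#' @return A `char_matrix` with those characters removed;
#'   `orig_index` keeps the mapping to the source matrix.
#' @export
exclude_characters <- function(M, exclude) {
  stopifnot(inherits(M, "char_matrix"))
  exclude <- as.integer(exclude)
  keep <- !(M$orig_index %in% exclude)
  if (all(keep)) return(M)
  character_matrix(M$mask[, keep, drop = FALSE], taxa = M$taxa,
                   nstates = M$nstates, weights = M$weights[keep],
                   ordered = M$ordered[keep],
                   orig_index = M$orig_index[keep])
}

.strip_nexus_comments <- function(txt) {
  # remove [...] comments (no nesting needed for the matrices we read)
  gsub("\\[[^]]*\\]", " ", txt)
}

.tokenize_row <- function(line) {
  # split "taxon  001(01)?0" into label + vector of cell tokens
  line <- trimws(line)
  if (grepl("^'", line)) {
    mm <- regmatches(line, regexec("^'([^']*)'\\s+(.*)$", line))[[1]]
    if (length(mm) < 3) stop("malformed quoted taxon row", call. = FALSE)
    lab <- mm[2]; seqs <- mm[3]
  } else {
    mm <- regmatches(line, regexec("^(\\S+)\\s+(.*)$", line))[[1]]
    if (length(mm) < 3) stop("malformed matrix row", call. = FALSE)
    lab <- mm[2]; seqs <- mm[3]
  }
  seqs <- gsub("\\s", "", seqs)
  toks <- regmatches(seqs, gregexpr("\\([^)]*\\)|\\{[^}]*\\}|.", seqs))[[1]]
  list(label = lab, tokens = toks)
}

.parse_matrix_rows <- function(lines, ntax, nchar_, nstates, file_tag) {
  cells <- list(); order <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || ln == ";") next
    row <- .tokenize_row(ln)
    if (!(row$label %in% order)) order <- c(order, row$label)
    cells[[row$label]] <- c(cells[[row$label]], row$tokens)
  }
  if (length(order) != ntax)
    stop(sprintf("%s: expected %d taxa, found %d", file_tag, ntax,
                 length(order)), call. = FALSE)
  mask <- matrix(0L, ntax, nchar_)
  for (i in seq_along(order)) {
    toks <- cells[[order[i]]]
    if (length(toks) != nchar_)
      stop(sprintf("%s: taxon '%s' has %d characters, expected %d",
                   file_tag, order[i], length(toks), nchar_), call. = FALSE)
    mask[i, ] <- vapply(toks, .symbols_to_mask, integer(1),
                        nstates = nstates)
  }
  rownames(mask) <- order
  mask
}

.read_nexus_matrix <- function(path) {
  txt <- .strip_nexus_comments(paste(readLines(path, warn = FALSE),
                                     collapse = "\n"))
  up <- toupper(txt)
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", up))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", up))
  if (is.na(ntax) || is.na(nchar_))
    stop("NEXUS: could not parse DIMENSIONS NTAX/NCHAR", call. = FALSE)
  nstates <- 10L
  if (grepl("SYMBOLS", up)) {
    sym <- sub('.*SYMBOLS\\s*=\\s*"([^"]*)".*', "\\1", txt,
               ignore.case = TRUE)
    sym <- gsub("\\s", "", sym)
    nstates <- max(10L, suppressWarnings(
      max(as.integer(strsplit(sym, "")[[1]]), na.rm = TRUE)) + 1L)
  }
  mstart <- regexpr("MATRIX", up)
  if (mstart < 0) stop("NEXUS: no MATRIX block", call. = FALSE)
  rest <- substr(txt, mstart + 6, nchar(txt))
  mend <- regexpr(";", rest)
  body <- substr(rest, 1, mend - 1)
  mask <- .parse_matrix_rows(strsplit(body, "\n")[[1]], ntax, nchar_,
                             nstates, "NEXUS")
  character_matrix(mask, taxa = rownames(mask), nstates = nstates)
}

.read_tnt_matrix <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regexec("xread[^']*(?:'[^']*')?\\s*(\\d+)\\s+(\\d+)([^;]*);", txt)
  mm <- regmatches(txt, m)[[1]]
  if (length(mm) < 4) stop("TNT: could not parse xread block", call. = FALSE)
  nchar_ <- as.integer(mm[2]); ntax <- as.integer(mm[3])
  mask <- .parse_matrix_rows(strsplit(mm[4], "\n")[[1]], ntax, nchar_,
                             10L, "TNT")
  character_matrix(mask, taxa = rownames(mask), nstates = 10L)
}

.read_csv_matrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE,
                 colClasses = "character")
  chr <- as.matrix(df)
  chr <- gsub("/", "", chr)
  character_matrix(chr, taxa = rownames(df), nstates = 10L)
}

#' Read a discrete character matrix (NEXUS, TNT or CSV)
#'
#' `?` and `-` both map to the full state set; polymorphisms written
#' `(01)` or `{01}` (or `0/1` in CSV) map to the listed set.  An
#' exclusion list of original 1-based character indices can be applied
#' at read time.
#'
#' @param path input file.
#' @param format `"auto"` (by extension/content), `"nexus"`, `"tnt"` or
#'   `"csv"`.
#' @param exclude integer vector of original character indices to drop.
#' @return A [character_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "nexus", "tnt", "csv"),
                        exclude = integer(0)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus")) "nexus"
    else if (ext %in% c("tnt", "ss")) "tnt"
    else if (ext == "csv") "csv"
    else {
      head_txt <- toupper(paste(readLines(path, n = 5, warn = FALSE),
                                collapse = " "))
      if (grepl("#NEXUS", head_txt)) "nexus"
      else if (grepl("XREAD", head_txt)) "tnt"
      else "csv"
    }
  }
  M <- switch(format,
              nexus = .read_nexus_matrix(path),
              tnt = .read_tnt_matrix(path),
              csv = .read_csv_matrix(path))
  exclude_characters(M, exclude)
}

#' Write a character matrix as a minimal NEXUS file
#'
#' @param M a [character_matrix()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_nexus <- function(M, path) {
  stopifnot(inherits(M, "char_matrix"))
  full <- bitwShiftL(1L, M$nstates) - 1L
  cell <- function(mask) {
    if (mask == full) return("?")
    st <- which(bitwAnd(mask, bitwShiftL(1L, 0:(M$nstates - 1L))) > 0L) - 1L
    if (length(st) == 1L) as.character(st)
    else paste0("(", paste(st, collapse = ""), ")")
  }
  rows <- vapply(seq_along(M$taxa), function(i)
    paste0(gsub("\\s", "_", M$taxa[i]), "  ",
           paste(vapply(M$mask[i, ], cell, character(1)), collapse = "")),
    character(1))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(M$taxa),
                       ncol(M$mask)),
               "  FORMAT SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
               "  MATRIX", paste0("    ", rows), "  ;", "END;"), path)
  invisible(path)
}

.mask_states <- function(mask, nstates) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(nstates - 1L))) > 0L) - 1L
}
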