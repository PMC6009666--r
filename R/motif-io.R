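#' Read and write JASPAR-style PWM text files
#'
#' The JASPAR text dialect is a `>id` header followed by four base rows,
#' either bare numbers or `A [ 12 3 0 ... ]` bracketed counts. Counts (or
#' probabilities) are normalized column-wise to probabilities on read.
#' Files may hold several records.
#'
#' @param path File path.
#' @return A named list of [pwm()] objects (singletons are still lists).
#' @export
read_jaspar_pwm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no '>' header found in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stop("record '", id, "' must have exactly 4 base rows, found ",
           length(body))
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[", " ", gsub("]", " ", l, fixed = TRUE), fixed = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("record '", id, "' has ragged rows (lengths ",
           paste(lens, collapse = ", "), ")")
    m <- do.call(rbind, rows)
    # order rows by their base prefix when present, else assume A,C,G,T
    prefixes <- toupper(substr(body, 1L, 1L))
    if (all(sort(prefixes) == BASES)) m <- m[match(BASES, prefixes), , drop = FALSE]
    m <- sweep(m, 2L, colSums(m), "/")
    out[[id]] <- pwm(id, m)
  }
  out
}

#' @param x A [pwm()] (or `composite_motif`).
#' @rdname read_jaspar_pwm
#' @export
write_jaspar_pwm <- function(x, path) {
  p <- .motif_pwm(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", p$id), con)
  for (b in BASES)
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(p$mat[b, ], digits = 6), collapse = " ")),
               con)
  invisible(path)
}

#' Read a PWM from the simple TSV matrix dialect
#'
#' A header line `A C G T` (optionally preceded by a position column named
#' `pos`) followed by one row of probabilities or counts per motif
#' position.
#'
#' @param path File path.
#' @param id Identifier for the motif (defaults to the file name).
#' @return A [pwm()].
#' @export
read_pwm_tsv <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  x <- utils::read.delim(path, check.names = FALSE)
  if (!all(BASES %in% names(x)))
    stop("PWM TSV needs columns A, C, G, T")
  m <- t(as.matrix(x[, BASES]))
  m <- sweep(m, 2L, colSums(m), "/")
  pwm(id, m)
}

#' Build a composite motif from a YAML definition
#'
#' The YAML file names the two halves, the orientation and the spacer, e.g.
#'
#' ```yaml
#' id: D0
#' orientation: DIV
#' spacer: -2
#' half1: core          # built-in source, a consensus string, or a file
#' half2: core
#' ```
#'
#' A half is resolved as a built-in monomer source (`core`, `homer`,
#' `full`), as an IUPAC consensus string, or as a path to a JASPAR-style
#' file (first record).
#'
#' @param path YAML file path.
#' @return A `composite_motif`.
#' @export
composite_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("orientation", "spacer", "half1")
  if (!all(need %in% names(cfg)))
    stop("composite YAML needs keys: ", paste(need, collapse = ", "))
  resolve_half <- function(spec) {
    if (spec %in% c("core", "homer", "full")) return(foxa1_monomer_pwm(spec))
    if (file.exists(spec)) return(read_jaspar_pwm(spec)[[1]])
    if (grepl("^[ACGTRYSWKMBDHVN]+$", toupper(spec)))
      return(pwm_from_consensus(spec))
    stop("cannot resolve half-site spec '", spec, "'")
  }
  h1 <- resolve_half(cfg$half1)
  h2 <- if (is.null(cfg$half2)) h1 else resolve_half(cfg$half2)
  build_composite(h1, h2, orientation = cfg$orientation,
                  spacer = as.integer(cfg$spacer),
                  id = if (is.null(cfg$id)) NULL else cfg$id)
}
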