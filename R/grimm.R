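# GRIMM-dialect genome files.
#
# A line starting ">" names a genome; each following non-empty line is one
# chromosome: whitespace-separated signed integers terminated by "$" (linear)
# or "@" (circular).  The unicode telomere notation "∘ g1 ... gk ∘" is
# accepted on input as an alternative way to write a linear chromosome.
# Lines starting "#" are comments.

#' Read genomes from a GRIMM-dialect file
#'
#' @param path path to a text file, or `NULL` if `text` is given.
#' @param text optional character vector of lines (instead of a file).
#' @return a named list of [genome()] objects.
#' @examples
#' g <- read_grimm(text = c(">A", "1 2 3 @"))
#' g$A
#' @export
read_grimm <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("read_grimm: give either path or text")
    text <- readLines(path, warn = FALSE, encoding = "UTF-8")
  }
  genomes <- list()
  cur_name <- NULL
  cur_chrs <- list()
  flush <- function() {
    if (is.null(cur_name)) return()
    if (length(cur_chrs) == 0L)
      stop("read_grimm: genome '", cur_name, "' has no chromosomes")
    genomes[[cur_name]] <<- genome(cur_chrs, name = cur_name)
  }
  for (i in seq_along(text)) {
    line <- trimws(text[i])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      flush()
      cur_name <- trimws(substring(line, 2L))
      if (cur_name == "") cur_name <- sprintf("genome_%d", length(genomes) + 1L)
      cur_chrs <- list()
      next
    }
    if (is.null(cur_name)) {
      cur_name <- "genome_1"
      cur_chrs <- list()
    }
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    linear <- NA
    if (toks[length(toks)] == "$") { linear <- TRUE;  toks <- toks[-length(toks)] }
    else if (toks[length(toks)] == "@") { linear <- FALSE; toks <- toks[-length(toks)] }
    if (length(toks) > 0L && toks[1L] == "∘" &&
        toks[length(toks)] == "∘") {
      if (!is.na(linear) && !linear)
        stop("read_grimm: line ", i, ": telomeres '∘' on a '@' chromosome")
      linear <- TRUE
      toks <- toks[-c(1L, length(toks))]
    }
    if (is.na(linear))
      stop("read_grimm: line ", i, ": chromosome must end in '$' (linear) or '@' ",
           "(circular), or be flanked by '∘'")
    if (length(toks) == 0L)
      stop("read_grimm: line ", i, ": empty chromosome")
    genes <- suppressWarnings(as.integer(toks))
    if (anyNA(genes)) {
      bad <- toks[which(is.na(genes))[1L]]
      stop("read_grimm: line ", i, ": token '", bad, "' is not a signed integer")
    }
    cur_chrs[[length(cur_chrs) + 1L]] <- chromosome(genes, linear = linear)
  }
  flush()
  if (length(genomes) == 0L) stop("read_grimm: no genomes found")
  genomes
}

#' Write genomes to a GRIMM-dialect file
#'
#' The canonical form uses "$"-terminated lines for linear chromosomes and
#' "@"-terminated lines for circular ones; [read_grimm()] round-trips this
#' form exactly.
#'
#' @param genomes a [genome()] or a (possibly named) list of genomes.
#' @param path output file path, or `NULL` to return the lines invisibly.
#' @return invisibly, the character vector of lines written.
#' @export
write_grimm <- function(genomes, path = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  nm <- names(genomes)
  lines <- character(0)
  for (k in seq_along(genomes)) {
    g <- genomes[[k]]
    stopifnot(inherits(g, "genome"))
    name <- if (!is.null(nm) && !is.na(nm[k]) && nzchar(nm[k])) nm[k]
            else if (!is.null(g$name)) g$name
            else sprintf("genome_%d", k)
    lines <- c(lines, paste0(">", name))
    for (ch in g$chromosomes) {
      lines <- c(lines, paste(c(ch$genes, if (ch$linear) "$" else "@"),
                              collapse = " "))
    }
  }
  if (!is.null(path)) writeLines(lines, path, useBytes = FALSE)
  invisible(lines)
}
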