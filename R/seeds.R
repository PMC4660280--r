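#' Read a seed list
#'
#' One identifier per line, UTF-8 plain text; blank lines and \code{#}
#' comments are dropped; duplicates are dropped with a warning, keeping the
#' order of first occurrence.
#'
#' @param path path to the seed-list file.
#' @param name process label (defaults to the file name without extension).
#' @return a [SeedList-class].
#' @export
readSeedList <- function(path, name = NULL) {
  if (!file.exists(path))
    stop("cannot read seed list: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  dup <- duplicated(x)
  if (any(dup))
    warning(sprintf("seed list \"%s\": dropped %d duplicate identifier(s): %s",
                    name, sum(dup),
                    paste(unique(x[dup]), collapse = ", ")))
  x <- x[!dup]
  if (length(x) == 0L)
    stop("seed list \"", name, "\" contains no identifiers")
  SeedList(x, name = name)
}

#' Write a seed list
#'
#' @param seeds a [SeedList-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSeedList <- function(seeds, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# seed list: %s", seedName(seeds)),
               seedMembers(seeds)), con, sep = "\n")
  invisible(path)
}
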