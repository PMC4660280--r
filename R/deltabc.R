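#' Differential betweenness centrality (delta BC)
#'
#' The cross-talk statistic: for every node of the union network,
#' \deqn{\Delta BC(v) = BC_{union}(v) - BC_{auto}(v) - BC_{mito}(v),}
#' where a node absent from a sub-network contributes 0 for that term (an
#' absent node has no betweenness there — reported as "-"/N/A in output).
#' High delta-BC marks nodes whose path-brokering role emerges only when the
#' two process networks are combined. All three tables must be unnormalized:
#' the subtraction is only dimensionally coherent in raw pair-count units,
#' because the three networks differ in size.
#'
#' The two sub-network arguments are conventionally called "auto" and "mito"
#' after the autophagy / mitochondrial-dysfunction application the statistic
#' was developed for; any two processes can be supplied.
#'
#' @param unionTab [CentralityTable-class] of the union network; must cover
#'   every node of the two sub-network tables (a sub-network node missing
#'   from the union is a fatal consistency error).
#' @param autoTab,mitoTab [CentralityTable-class]s of the two sub-networks.
#' @return data frame with one row per union-network node, ordered by rank:
#'   \code{node}, \code{bc_auto}, \code{bc_mito} (NA when the node is absent
#'   from that sub-network), \code{bc_union}, \code{delta_bc},
#'   \code{in_auto}, \code{in_mito}, and \code{rank} (1..N by descending
#'   \code{delta_bc}, ties broken by node identifier ascending).
#' @seealso [rankTargets()], [writeDeltaBC()]
#' @export
deltaBC <- function(unionTab, autoTab, mitoTab) {
  for (tab in list(unionTab, autoTab, mitoTab)) {
    stopifnot(is(tab, "CentralityTable"))
    if (isNormalized(tab))
      stop("delta BC requires unnormalized centrality tables")
  }
  bu <- bcValues(unionTab)
  ba <- bcValues(autoTab)
  bm <- bcValues(mitoTab)
  nodes <- names(bu)
  stray <- setdiff(union(names(ba), names(bm)), nodes)
  if (length(stray))
    stop("sub-network node(s) missing from the union table: ",
         paste(utils::head(stray, 10), collapse = ", "))

  in_auto <- nodes %in% names(ba)
  in_mito <- nodes %in% names(bm)
  bc_auto <- ifelse(in_auto, ba[nodes], NA_real_)
  bc_mito <- ifelse(in_mito, bm[nodes], NA_real_)
  delta <- unname(bu) -
    ifelse(in_auto, bc_auto, 0) -
    ifelse(in_mito, bc_mito, 0)

  df <- data.frame(node = nodes,
                   bc_auto = unname(bc_auto), bc_mito = unname(bc_mito),
                   bc_union = unname(bu), delta_bc = unname(delta),
                   in_auto = in_auto, in_mito = in_mito,
                   stringsAsFactors = FALSE)
  ord <- order(-df$delta_bc, df$node)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Top-ranked cross-talk targets
#'
#' @param records ranked data frame from [deltaBC()].
#' @param topK number of top rows to return (at least 1).
#' @return the first \code{topK} rows (fewer if the table is shorter), in
#'   rank order.
#' @export
rankTargets <- function(records, topK) {
  if (!is.numeric(topK) || length(topK) != 1L || topK < 1)
    stop("'topK' must be a positive integer")
  records <- records[order(records$rank), , drop = FALSE]
  utils::head(records, n = as.integer(topK))
}

#' Write the ranked delta-BC table as TSV
#'
#' Columns \code{node}, \code{bc_auto}, \code{bc_mito}, \code{bc_union},
#' \code{delta_bc}, \code{in_auto}, \code{in_mito}, \code{rank}; rows in rank
#' order; a \code{-} marks a betweenness that does not exist because the node
#' is absent from that sub-network.
#'
#' @param records data frame from [deltaBC()] or [rankTargets()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeDeltaBC <- function(records, path) {
  out <- records[, c("node", "bc_auto", "bc_mito", "bc_union", "delta_bc",
                     "in_auto", "in_mito", "rank")]
  fmt <- function(x) vapply(x, function(v)
    if (is.na(v)) "-" else format(v, trim = TRUE, scientific = FALSE),
    character(1))
  out$bc_auto <- fmt(out$bc_auto)
  out$bc_mito <- fmt(out$bc_mito)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")),
             con, sep = "\n")
  invisible(path)
}
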