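#' Configure an end-to-end cross-talk run
#'
#' @param mitabPath path to the MITAB interaction table.
#' @param seedListPaths named character vector of exactly two seed-list
#'   files; the names are the process labels (default \code{auto},
#'   \code{mito}). The differential statistic is defined for exactly two
#'   processes.
#' @param outputDir directory the artifacts are written under (created if
#'   missing).
#' @param curation a [CurationPolicy-class].
#' @param idPreference identifier preference order, see [mitabDialect()].
#' @param topK number of top-ranked targets echoed in the run summary.
#' @param normalizedReport also write display-normalized centrality tables.
#' @param unionCompletion \code{"background"} (default) or \code{"none"},
#'   see [unionNetwork()].
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(mitabPath, seedListPaths, outputDir,
                      curation = curationPolicy(),
                      idPreference = c("alias", "uid"),
                      topK = 10L, normalizedReport = FALSE,
                      unionCompletion = c("background", "none")) {
  if (is.null(names(seedListPaths)))
    names(seedListPaths) <- c("auto", "mito")[seq_along(seedListPaths)]
  new("RunConfig", mitabPath = mitabPath,
      seedListPaths = seedListPaths,
      curation = curation,
      idPreference = idPreference,
      topK = as.integer(topK),
      outputDir = outputDir,
      normalizedReport = normalizedReport,
      unionCompletion = match.arg(unionCompletion))
}

#' Read a run configuration from YAML
#'
#' Expected keys: \code{mitab}, \code{seeds} (mapping of exactly two process
#' labels to file paths), \code{output_dir}; optional \code{top_k},
#' \code{normalized_report}, \code{union_completion} and a \code{curation}
#' mapping with \code{taxid}, \code{predicted_codes}, \code{drop_self_loops},
#' \code{require_both_taxa_match}, \code{id_preference}.
#'
#' @param path path to the YAML file.
#' @return a validated [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  for (key in c("mitab", "seeds", "output_dir"))
    if (is.null(y[[key]]))
      stop("run config is missing required key '", key, "'")
  cur <- y$curation
  policy <- curationPolicy(
    requiredTaxid = if (is.null(cur$taxid)) 9606L else cur$taxid,
    predictedMethodCodes = if (is.null(cur$predicted_codes))
      predictedMethodCodes() else as.character(cur$predicted_codes),
    dropSelfLoops = if (is.null(cur$drop_self_loops)) TRUE
      else cur$drop_self_loops,
    requireBothTaxaMatch = if (is.null(cur$require_both_taxa_match)) TRUE
      else cur$require_both_taxa_match)
  runConfig(
    mitabPath = y$mitab,
    seedListPaths = unlist(y$seeds),
    outputDir = y$output_dir,
    curation = policy,
    idPreference = if (is.null(cur$id_preference)) c("alias", "uid")
      else as.character(cur$id_preference),
    topK = if (is.null(y$top_k)) 10L else y$top_k,
    normalizedReport = isTRUE(y$normalized_report),
    unionCompletion = if (is.null(y$union_completion)) "background"
      else y$union_completion)
}

#' Run the cross-talk pipeline end to end
#'
#' Curate the MITAB table, build the background network, sample one
#' sub-network per seed list, form the union, compute betweenness on all
#' three networks, compute and rank delta BC. All artifacts are written
#' under the configured output directory; identical configuration and inputs
#' produce byte-identical outputs (the analysis is fully deterministic — all
#' randomness in this package lives in the synthetic generator).
#'
#' Files written: \code{curated_edges.tsv}, per-process
#' \code{subnetwork_<label>.tsv/.graphml} and \code{sampling_<label>.tsv},
#' \code{union.graphml} (with \code{bc_union} and \code{delta_bc} node
#' attributes), \code{bc_<label>.tsv} for all three networks (plus
#' \code{bc_<label>_normalized.tsv} when requested), the ranked table
#' \code{delta_bc_ranked.tsv}, and \code{manifest.json} (configuration echo,
#' input MD5 hashes, node/edge/record counts at every stage).
#'
#' @param config a [RunConfig-class], see [runConfig()] / [readRunConfig()].
#' @return invisibly, a list with the in-memory artifacts: \code{records},
#'   \code{curated}, \code{background}, \code{subnetworks}, \code{reports},
#'   \code{union}, \code{tables}, \code{delta}, \code{top}, \code{manifest}.
#' @export
runCrosstalk <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  for (p in c(config@mitabPath, config@seedListPaths))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  out <- config@outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  labels <- names(config@seedListPaths)

  message("[parse] reading ", config@mitabPath)
  dialect <- mitabDialect(idPreference = config@idPreference)
  records <- readMitab(config@mitabPath, dialect)

  message("[curate] applying curation policy")
  curated <- curateInteractions(records, config@curation)

  message("[graph] building background network")
  background <- buildGraph(curated, label = "background")
  writeEdgeList(background, file.path(out, "curated_edges.tsv"))

  subnetworks <- list()
  reports <- list()
  for (lab in labels) {
    message("[sample] process \"", lab, "\"")
    seeds <- readSeedList(config@seedListPaths[[lab]], name = lab)
    res <- sampleShortestPaths(background, seeds)
    subnetworks[[lab]] <- res$network
    reports[[lab]] <- res$report
    writeEdgeList(res$network, file.path(out, sprintf("subnetwork_%s.tsv",
                                                      lab)))
    writeGraphML(res$network, file.path(out, sprintf("subnetwork_%s.graphml",
                                                     lab)))
    writeSamplingReport(res$report, file.path(out, sprintf("sampling_%s.tsv",
                                                           lab)))
  }

  message("[union] forming the union network (completion: ",
          config@unionCompletion, ")")
  un <- unionNetwork(subnetworks[[1]], subnetworks[[2]],
                     background = if (config@unionCompletion == "background")
                       background else NULL)

  message("[bc] computing betweenness on both sub-networks and the union")
  tables <- list()
  for (net in c(subnetworks, list(union = un))) {
    tab <- betweennessTable(net, normalized = FALSE)
    tables[[networkLabel(net)]] <- tab
    writeCentrality(tab, file.path(out, sprintf("bc_%s.tsv",
                                                networkLabel(net))))
    if (config@normalizedReport)
      writeCentrality(betweennessTable(net, normalized = TRUE),
                      file.path(out, sprintf("bc_%s_normalized.tsv",
                                             networkLabel(net))))
  }

  message("[delta] computing and ranking delta BC")
  delta <- deltaBC(tables$union, tables[[labels[1]]], tables[[labels[2]]])
  writeDeltaBC(delta, file.path(out, "delta_bc_ranked.tsv"))
  writeGraphML(un, file.path(out, "union.graphml"),
               nodeAttrs = list(
                 bc_union = bcValues(tables$union),
                 delta_bc = stats::setNames(delta$delta_bc, delta$node)))
  top <- rankTargets(delta, config@topK)
  message(sprintf("[done] top %d of %d nodes by delta BC: %s",
                  nrow(top), nrow(delta),
                  paste(sprintf("%s (%.4g)", top$node, top$delta_bc),
                        collapse = ", ")))

  manifest <- list(
    config = list(
      mitab = config@mitabPath,
      seeds = as.list(config@seedListPaths),
      curation = list(
        taxid = config@curation@requiredTaxid,
        predicted_codes = config@curation@predictedMethodCodes,
        drop_self_loops = config@curation@dropSelfLoops,
        require_both_taxa_match = config@curation@requireBothTaxaMatch),
      id_preference = config@idPreference,
      top_k = config@topK,
      normalized_report = config@normalizedReport,
      union_completion = config@unionCompletion,
      isolated_seeds_included = TRUE),
    input_md5 = as.list(stats::setNames(
      unname(tools::md5sum(c(config@mitabPath,
                             unname(config@seedListPaths)))),
      c("mitab", names(config@seedListPaths)))),
    counts = c(
      curationReport(curated),
      list(background_nodes = numNodes(background),
           background_edges = numEdges(background)),
      stats::setNames(
        lapply(labels, function(l) list(
          nodes = numNodes(subnetworks[[l]]),
          edges = numEdges(subnetworks[[l]]),
          seeds_found = length(reports[[l]]@seedsFound),
          seeds_missing = length(reports[[l]]@seedsMissing),
          pairs_connected = reports[[l]]@pairsConnected,
          pairs_disconnected = reports[[l]]@pairsDisconnected)),
        paste0("subnetwork_", labels)),
      list(union_nodes = numNodes(un), union_edges = numEdges(un))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(records = records, curated = curated,
                 background = background, subnetworks = subnetworks,
                 reports = reports, union = un, tables = tables,
                 delta = delta, top = top, manifest = manifest))
}
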