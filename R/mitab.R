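#' PSI-MI TAB column dialect
#'
#' Maps the columns a MITAB file keeps its fields in. The defaults follow the
#' common 15-column core shared by MITAB 2.5/2.6/2.7: unique identifiers in
#' columns 1-2, aliases in 5-6, interaction detection method in 7, interactor
#' taxa in 10-11. iRefIndex-style distributions keep extra columns to the
#' right, which are ignored.
#'
#' @param uidA,uidB,aliasA,aliasB,method,taxidA,taxidB 1-based column indices.
#' @param header whether the first line is a header (dropped).
#' @param idPreference order in which identifier sources are tried when
#'   naming a node: \code{"alias"} (gene-symbol-style alias column, preferred
#'   default because it is the namespace targets are reported in) and/or
#'   \code{"uid"} (raw unique identifier). The first non-missing source wins;
#'   two records are merged to one node only when they resolve to the same
#'   preferred identifier.
#' @return a list of class \code{"mitabDialect"}.
#' @export
mitabDialect <- function(uidA = 1L, uidB = 2L, aliasA = 5L, aliasB = 6L,
                         method = 7L, taxidA = 10L, taxidB = 11L,
                         header = TRUE, idPreference = c("alias", "uid")) {
  idPreference <- match.arg(idPreference, c("alias", "uid"),
                            several.ok = TRUE)
  structure(list(uidA = uidA, uidB = uidB, aliasA = aliasA, aliasB = aliasB,
                 method = method, taxidA = taxidA, taxidB = taxidB,
                 header = header, idPreference = idPreference),
            class = "mitabDialect")
}

## MITAB field grammar: "db:accession(description)|alternative|..."
## Keep the first |-separated entry, strip the db prefix and description.
.mitabField <- function(x) {
  x <- trimws(x)
  x[x == "-" | x == ""] <- NA_character_
  x <- sub("\\|.*$", "", x)
  x <- sub("^[^:(]*:", "", x)
  x <- sub("\\(.*\\)\\s*$", "", x)
  x <- gsub("\"", "", x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

.mitabTaxid <- function(x) {
  m <- regmatches(x, regexpr("taxid:-?[0-9]+", x))
  out <- rep(NA_integer_, length(x))
  hit <- grepl("taxid:-?[0-9]+", x)
  out[hit] <- as.integer(sub("taxid:", "", m))
  out
}

.mitabMethod <- function(x) {
  out <- rep(NA_character_, length(x))
  hit <- grepl("MI:[0-9]{4}", x)
  out[hit] <- regmatches(x, regexpr("MI:[0-9]{4}", x))[seq_len(sum(hit))]
  out
}

#' Read a MITAB interaction table
#'
#' Parses a PSI-MI TAB file into one record per data line. Comment lines
#' (leading \code{#}) are skipped; a \code{-} field means unknown. Taxon
#' fields of the form \code{taxid:9606(Homo sapiens)} reduce to the integer;
#' detection methods reduce to their \code{MI:nnnn} code. Each record is also
#' given working identifiers \code{id_a}/\code{id_b} chosen from the alias or
#' uid columns per the dialect's preference order.
#'
#' @param path path to a tab-separated MITAB file.
#' @param dialect a [mitabDialect()] describing the column layout.
#' @return data frame with columns \code{uid_a}, \code{uid_b}, \code{alias_a},
#'   \code{alias_b}, \code{taxid_a}, \code{taxid_b}, \code{detection_method},
#'   \code{id_a}, \code{id_b} and \code{source_line} (the 1-based file line).
#'   Lines with too few columns are skipped with a warning, never silently.
#' @seealso [curateInteractions()], [buildGraph()]
#' @export
readMitab <- function(path, dialect = mitabDialect()) {
  if (!file.exists(path))
    stop("cannot read MITAB file: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  if (dialect$header && length(lines) >= 1L) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]

  need <- max(dialect$uidA, dialect$uidB, dialect$aliasA, dialect$aliasB,
              dialect$method, dialect$taxidA, dialect$taxidB)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < need
  if (any(short)) {
    warning(sprintf("skipped %d line(s) with fewer than %d columns (lines %s)",
                    sum(short), need,
                    paste(utils::head(lineno[short], 10), collapse = ", ")))
    fields <- fields[!short]
    lineno <- lineno[!short]
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  if (length(fields) == 0L) col <- function(i) character(0)

  rec <- data.frame(
    uid_a = .mitabField(col(dialect$uidA)),
    uid_b = .mitabField(col(dialect$uidB)),
    alias_a = .mitabField(col(dialect$aliasA)),
    alias_b = .mitabField(col(dialect$aliasB)),
    taxid_a = .mitabTaxid(col(dialect$taxidA)),
    taxid_b = .mitabTaxid(col(dialect$taxidB)),
    detection_method = .mitabMethod(col(dialect$method)),
    source_line = lineno,
    stringsAsFactors = FALSE)

  pick <- function(alias, uid) {
    id <- rep(NA_character_, length(alias))
    for (src in dialect$idPreference) {
      cand <- switch(src, alias = alias, uid = uid)
      id[is.na(id)] <- cand[is.na(id)]
    }
    id
  }
  rec$id_a <- pick(rec$alias_a, rec$uid_a)
  rec$id_b <- pick(rec$alias_b, rec$uid_b)
  bad <- is.na(rec$id_a) | is.na(rec$id_b)
  if (any(bad)) {
    warning(sprintf("skipped %d record(s) with no resolvable identifier",
                    sum(bad)))
    rec <- rec[!bad, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' PSI-MI codes treated as computational predictions
#'
#' The default prediction filter: \code{MI:0063} ("interaction prediction")
#' and its prediction-branch descendants. Override through
#' [curationPolicy()] when a different ontology slice is wanted.
#'
#' @return character vector of PSI-MI term codes.
#' @export
predictedMethodCodes <- function() .defaultPredictedCodes

.defaultPredictedCodes <- c(
  "MI:0063",  # interaction prediction
  "MI:0064",  # interologs mapping
  "MI:0085",  # phylogenetic profile
  "MI:0087",  # predictive text mining
  "MI:0105")  # structure based prediction

#' Curate parsed MITAB records
#'
#' Applies, in order: the taxon filter (both interactors must match the
#' required taxon; unknown taxa drop the record when
#' \code{requireBothTaxaMatch}), the predicted-interaction filter (detection
#' method in the policy's predicted codes), and the self-interaction filter.
#' Counts per filter are reported with [message()] and attached as the
#' \code{"curation_report"} attribute (see [curationReport()]); the report
#' gives both surviving record and unique node-pair counts, since an
#' interaction database may count either.
#'
#' @param records data frame from [readMitab()].
#' @param policy a [CurationPolicy-class].
#' @return the filtered records, same columns, with a report attribute.
#' @export
curateInteractions <- function(records, policy = curationPolicy()) {
  n_in <- nrow(records)

  tax_ok <- records$taxid_a %in% policy@requiredTaxid &
    records$taxid_b %in% policy@requiredTaxid
  if (!policy@requireBothTaxaMatch) {
    tax_ok <- tax_ok |
      ((is.na(records$taxid_a) | records$taxid_a == policy@requiredTaxid) &
       (is.na(records$taxid_b) | records$taxid_b == policy@requiredTaxid))
  }
  records <- records[tax_ok, , drop = FALSE]
  n_tax <- nrow(records)

  pred <- !is.na(records$detection_method) &
    records$detection_method %in% policy@predictedMethodCodes
  records <- records[!pred, , drop = FALSE]
  n_pred <- nrow(records)

  if (policy@dropSelfLoops)
    records <- records[records$id_a != records$id_b, , drop = FALSE]
  n_out <- nrow(records)

  pair <- unique(paste(pmin(records$id_a, records$id_b),
                       pmax(records$id_a, records$id_b)))
  report <- list(
    records_in = n_in,
    dropped_taxon = n_in - n_tax,
    dropped_predicted = n_tax - n_pred,
    dropped_self = n_pred - n_out,
    records_out = n_out,
    unique_pairs_out = length(pair),
    unique_proteins_out = length(unique(c(records$id_a, records$id_b))))
  message(sprintf(
    paste0("curation: %d records in; dropped %d non-taxon, %d predicted, ",
           "%d self; %d records out (%d unique pairs, %d proteins)"),
    report$records_in, report$dropped_taxon, report$dropped_predicted,
    report$dropped_self, report$records_out, report$unique_pairs_out,
    report$unique_proteins_out))
  rownames(records) <- NULL
  attr(records, "curation_report") <- report
  records
}

#' @rdname curateInteractions
#' @param x curated records.
#' @return `curationReport`: the named list of filter counts.
#' @export
curationReport <- function(x) attr(x, "curation_report")

#' Build a protein network from curated records
#'
#' Nodes are all identifiers appearing in any record; edges are deduplicated
#' unordered pairs ((a,b) and (b,a) collapse to one edge, multiplicity is
#' discarded). Self pairs, if still present, are dropped by the simple-graph
#' constraint.
#'
#' @param records data frame with \code{id_a}/\code{id_b} columns
#'   (from [readMitab()] / [curateInteractions()]).
#' @param label provenance label for the network.
#' @return a [ProteinNetwork-class].
#' @export
buildGraph <- function(records, label = "background") {
  if (nrow(records) == 0L) {
    warning("no records: building an empty \"", label, "\" network")
    return(ProteinNetwork(NULL, label = label))
  }
  ProteinNetwork(cbind(records$id_a, records$id_b), label = label)
}

.psimiMethodLabels <- c(
  "MI:0018" = "two hybrid",
  "MI:0006" = "anti bait coimmunoprecipitation",
  "MI:0004" = "affinity chromatography technology",
  "MI:0096" = "pull down",
  "MI:0063" = "interaction prediction")

.mitabHeader <- paste(
  "#ID(s) interactor A", "ID(s) interactor B",
  "Alt. ID(s) interactor A", "Alt. ID(s) interactor B",
  "Alias(es) interactor A", "Alias(es) interactor B",
  "Interaction detection method(s)", "Publication 1st author(s)",
  "Publication Identifier(s)", "Taxid interactor A", "Taxid interactor B",
  "Interaction type(s)", "Source database(s)", "Interaction identifier(s)",
  "Confidence value(s)", sep = "\t")

.taxonLabels <- c("9606" = "Homo sapiens", "10090" = "Mus musculus",
                  "10116" = "Rattus norvegicus",
                  "7227" = "Drosophila melanogaster",
                  "4932" = "Saccharomyces cerevisiae")

#' Write a network as a MITAB 2.6 table
#'
#' Serialises one row per edge in the 15-column MITAB core. By default every
#' row is human (\code{taxid:9606}) with a two-hybrid detection method; when
#' a [SyntheticTruth-class] carrying edge annotations is supplied (see
#' [generatePlantedBridge()]), the annotated taxa and methods are written
#' instead, so that decoy rows exercise the curation filters on re-parse.
#'
#' @param net a [ProteinNetwork-class].
#' @param path output file path.
#' @param truth optional [SyntheticTruth-class] with \code{edgeAnnotations}.
#' @return the path, invisibly.
#' @export
writeMitab <- function(net, path, truth = NULL) {
  et <- edgeTable(net)
  if (!is.null(truth)) {
    ann <- truth@edgeAnnotations
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    idx <- match(key(et$a, et$b), key(ann$a, ann$b))
    if (anyNA(idx))
      stop("edge annotations do not cover every network edge")
    ann <- ann[idx, , drop = FALSE]
  } else {
    ann <- data.frame(a = et$a, b = et$b,
                      taxid_a = rep(9606L, nrow(et)),
                      taxid_b = rep(9606L, nrow(et)),
                      method = rep("MI:0018", nrow(et)),
                      stringsAsFactors = FALSE)
  }
  taxf <- function(t) sprintf("taxid:%d(%s)", t,
                              ifelse(is.na(.taxonLabels[as.character(t)]),
                                     "unknown",
                                     .taxonLabels[as.character(t)]))
  methf <- function(m) sprintf('psi-mi:"%s"(%s)', m,
                               ifelse(is.na(.psimiMethodLabels[m]),
                                      "unspecified method",
                                      .psimiMethodLabels[m]))
  rows <- paste(
    paste0("syndb:", et$a), paste0("syndb:", et$b), "-", "-",
    sprintf("syndb:%s(gene name)", et$a),
    sprintf("syndb:%s(gene name)", et$b),
    methf(ann$method), "-", "pubmed:00000000",
    taxf(ann$taxid_a), taxf(ann$taxid_b),
    'psi-mi:"MI:0915"(physical association)', "syndb", "-", "-",
    sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(.mitabHeader, rows), con, sep = "\n")
  invisible(path)
}
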