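# Plain-text persistence: one delimited matrix per subject, a manifest
# table, a region-label file, and JSON sidecars carrying the metadata
# needed to re-derive every artifact (R, edge ordering, seed, parameters).

#' Write a cohort to a directory
#'
#' Writes one tab-delimited T x R matrix per subject (`<subject_id>.tsv`),
#' a manifest (`manifest.tsv`: subject_id, group as `patient`/`control`,
#' path), a region-label file (`region_labels.txt`, one name per line) and
#' a metadata sidecar (`cohort.json`: TR, dimensions, edge ordering).
#'
#' @param cohort an [FcCohort-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "FcCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- subjectIds(cohort)
  paths <- paste0(ids, ".tsv")
  for (s in seq_along(ids)) {
    write.table(
      format(subjectSeries(cohort, s), digits = 17, scientific = TRUE,
             trim = TRUE),
      file.path(dir, paths[s]),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  manifest <- data.frame(
    subject_id = ids,
    group = ifelse(groupLabels(cohort) == -1L, "patient", "control"),
    path = paths,
    stringsAsFactors = FALSE
  )
  write.table(manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(regionLabels(cohort), file.path(dir, "region_labels.txt"))
  jsonlite::write_json(
    list(trSeconds = trSeconds(cohort),
         nRegions = nRegions(cohort),
         nTimepoints = nrow(subjectSeries(cohort, 1)),
         edgeOrder = "row-major upper triangle, i < j"),
    file.path(dir, "cohort.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Reads the layout written by [writeCohort()]. Group tokens other than
#' `patient`/`control`, duplicate subject ids, unresolvable paths and
#' inconsistent matrix dimensions are rejected with explicit messages.
#'
#' @param dir directory containing `manifest.tsv`, `region_labels.txt` and
#'   the per-subject matrices
#' @param trSeconds sampling interval; defaults to the value recorded in
#'   `cohort.json`
#' @return an [FcCohort-class]
#' @export
readCohort <- function(dir, trSeconds = NULL) {
  manifestPath <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifestPath)) stop("manifest.tsv not found in ", dir)
  manifest <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  badGroup <- !manifest$group %in% c("patient", "control")
  if (any(badGroup))
    stop("unknown group token in manifest row(s): ",
         paste(which(badGroup), collapse = ", "))
  if (anyDuplicated(manifest$subject_id))
    stop("duplicate subject ids in manifest")
  labels <- readLines(file.path(dir, "region_labels.txt"))
  if (is.null(trSeconds)) {
    metaPath <- file.path(dir, "cohort.json")
    if (!file.exists(metaPath))
      stop("trSeconds not given and cohort.json not found")
    trSeconds <- jsonlite::read_json(metaPath)$trSeconds
  }
  series <- lapply(seq_len(nrow(manifest)), function(r) {
    p <- file.path(dir, manifest$path[r])
    if (!file.exists(p))
      stop("series file not found for subject ", manifest$subject_id[r],
           ": ", p)
    m <- as.matrix(utils::read.delim(p, header = FALSE))
    if (ncol(m) != length(labels))
      stop("subject ", manifest$subject_id[r], " has ", ncol(m),
           " regions; label table has ", length(labels))
    m
  })
  FcCohort(
    series = series,
    group = ifelse(manifest$group == "patient", -1L, 1L),
    subjectIds = manifest$subject_id,
    regionLabels = labels,
    trSeconds = trSeconds
  )
}

#' Write the edge-feature table
#'
#' Subjects x features matrix as TSV plus a JSON sidecar recording R, the
#' edge ordering convention and the group labels.
#'
#' @param dataset an [FcDataset-class]
#' @param path output TSV path; the sidecar gets extension `.json`
#' @return `path`, invisibly
#' @export
writeFeatureTable <- function(dataset, path) {
  stopifnot(is(dataset, "FcDataset"))
  X <- featureMatrix(dataset)
  df <- data.frame(subject_id = subjectIds(dataset),
                   group = groupLabels(dataset),
                   format(X, digits = 17, trim = TRUE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("e", seq_len(ncol(X)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(nRegions = nRegions(dataset),
         nFeatures = ncol(X),
         edgeOrder = "row-major upper triangle, i < j",
         regionLabels = regionLabels(dataset)),
    sub("\\.tsv$", ".json", path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a simulation configuration from JSON or YAML
#'
#' The file may contain any subset of the [simConfig()] arguments;
#' `plantedEdges` is given as a list/array of objects with fields `i`, `j`,
#' `delta`. YAML requires the \pkg{yaml} package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file
#' @return a validated `"fcSimConfig"`
#' @export
readSimConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else stop("unsupported configuration format: .", ext)
  if (!is.null(raw$plantedEdges))
    raw$plantedEdges <- as.data.frame(raw$plantedEdges)
  if (!is.null(raw$bandLimit)) raw$bandLimit <- unlist(raw$bandLimit)
  do.call(simConfig, raw)
}

#' Write a cross-validation report as JSON
#'
#' Per-fold predictions and selections, confusion counts, GR/SS/SC and the
#' consensus/union feature sets.
#'
#' @param cv an [FcCv-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCvReport <- function(cv, path) {
  stopifnot(is(cv, "FcCv"))
  jsonlite::write_json(
    list(
      params = cv@params,
      counts = as.list(cv@counts),
      metrics = as.list(cv@metrics),
      predictions = cv@predictions,
      consensus = cv@consensus,
      union = cv@union,
      selections = lapply(cv@folds, `[[`, "selection")
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
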