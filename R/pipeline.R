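#' Pipeline configuration
#'
#' Serializable bundle of every threshold the end-to-end run uses; a copy is
#' written next to the outputs so a run is self-describing.
#'
#' @param seed Integer seed driving the whole run.
#' @param outputDir Output directory (created if absent).
#' @param nPerSubfamily Query sequences per subfamily (default 10).
#' @param nSeeds Seed sequences per subfamily (default 3).
#' @param nDecoys GDH-like decoys mixed into the queries (default 0).
#' @param subfamilies CDD accessions to simulate (default all 19).
#' @param interIdentity,intraIdentity Generator calibration targets.
#' @param lengthThreshold Minimum sequence length, exclusive (default 200).
#' @param insertMinima HOT insert-length minima (default `c(15, 9)`).
#' @param gggsTolerance GGGS motif mismatch tolerance (default 1).
#' @param minMarginFrac Classification margin fraction (default 0.05).
#' @param bootstrapReplicates Bootstrap replicates for the tree stage
#'   (default 100 for the pipeline; use 500 for a full analysis).
#' @param treeMaxPerSubfamily Queries per subfamily entering the tree
#'   (default 4; distance bootstrapping on every query is rarely needed).
#' @param logoPositions Reference positions for the logo stage (default the
#'   diagnostic set 81, 242, 246, 330, 357).
#' @param smallSampleCorrection Logo small-sample correction (default
#'   `FALSE`).
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1, outputDir = tempfile("feadh_run_"),
                           nPerSubfamily = 10, nSeeds = 3, nDecoys = 0,
                           subfamilies = NULL, interIdentity = 20,
                           intraIdentity = 70, lengthThreshold = 200,
                           insertMinima = c(15L, 9L), gggsTolerance = 1,
                           minMarginFrac = 0.05, bootstrapReplicates = 100,
                           treeMaxPerSubfamily = 4,
                           logoPositions = c(81, 242, 246, 330, 357),
                           smallSampleCorrection = FALSE) {
  structure(list(seed = as.integer(seed), outputDir = outputDir,
                 nPerSubfamily = as.integer(nPerSubfamily),
                 nSeeds = as.integer(nSeeds), nDecoys = as.integer(nDecoys),
                 subfamilies = subfamilies, interIdentity = interIdentity,
                 intraIdentity = intraIdentity,
                 lengthThreshold = lengthThreshold,
                 insertMinima = as.integer(insertMinima),
                 gggsTolerance = gggsTolerance,
                 minMarginFrac = minMarginFrac,
                 bootstrapReplicates = as.integer(bootstrapReplicates),
                 treeMaxPerSubfamily = as.integer(treeMaxPerSubfamily),
                 logoPositions = as.integer(logoPositions),
                 smallSampleCorrection = smallSampleCorrection),
            class = "PipelineConfig")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate - length-filter - annotate - classify - tree - logo
#' as one deterministic run and writes the report bundle into
#' `config$outputDir`: `queries.fasta` and `truth.tsv` (the simulated data),
#' `annotation.tsv`, `classification.tsv`, `phyletic.json`,
#' `phyletic_table.tsv`, `tree.nwk`, `logo.tsv`, `summary.txt` (headline
#' percentages, truncated and at one decimal) and `config.json`. A failure
#' in any stage aborts with the stage name.
#'
#' @param config A `"PipelineConfig"` from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results (`simulation`,
#'   `annotation`, `classification`, `phyletic`, `tree`, `logo`) and the
#'   vector of written `paths`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outputDir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  registry <- loadRegistry()
  sim <- stage("simulate", {
    gen <- generatorConfig(seed = config$seed,
                           nPerSubfamily = config$nPerSubfamily,
                           interIdentity = config$interIdentity,
                           intraIdentity = config$intraIdentity,
                           subfamilies = config$subfamilies,
                           registry = registry)
    simulateFeadhData(gen, registry = registry, nSeeds = config$nSeeds,
                      nDecoys = config$nDecoys)
  })
  queries <- sim$queries$records
  truth <- sim$queries$truth
  if (!is.null(sim$decoys) && length(sim$decoys$records)) {
    queries <- feadhRecords(
      c(as.character(queries), as.character(sim$decoys$records)),
      c(names(queries), names(sim$decoys$records)),
      taxon_group = c(mcols(queries)$taxon_group,
                      mcols(sim$decoys$records)$taxon_group))
    truth <- rbind(truth, sim$decoys$truth)
  }
  writeFeadhFasta(queries, out("queries.fasta"))
  writeTsv(truth, out("truth.tsv"))

  filtered <- stage("filter",
                    filterByLength(queries, config$lengthThreshold))
  ann <- stage("annotate",
               annotateSequences(filtered, sim$reference,
                                 insertMinima = config$insertMinima,
                                 gggsTolerance = config$gggsTolerance))
  writeTsv(ann, out("annotation.tsv"))

  cls <- stage("classify", {
    seedSets <- buildSeedSets(sim$seeds$records, sim$seeds$truth$subfamily)
    classifySequences(filtered, seedSets, annotations = ann,
                      minMarginFrac = config$minMarginFrac)
  })
  writeTsv(cls, out("classification.tsv"))

  phyletic <- stage("phyletic", summarizePhyletic(cls, filtered))
  jsonlite::write_json(
    list(counts = as.data.frame.table(phyletic$counts,
                                      responseName = "count"),
         total_assigned = phyletic$total_assigned,
         eukaryote_total = phyletic$eukaryote_total,
         subfamily_shares = phyletic$subfamily_shares,
         animal_hot = phyletic$animal_hot,
         fungi_hot = phyletic$fungi_hot),
    out("phyletic.json"), auto_unbox = TRUE, digits = NA)
  renderPhyleticTable(phyletic, out("phyletic_table.tsv"))

  treeFit <- stage("tree", {
    keep <- unlist(lapply(split(truth$id, truth$abbreviation), function(x)
      utils::head(x, config$treeMaxPerSubfamily)))
    sub <- filtered[names(filtered) %in% keep]
    bootstrapSupport(sub, sim$reference,
                     nReplicates = config$bootstrapReplicates,
                     seed = config$seed)
  })
  writeNewick(treeFit, out("tree.nwk"))

  logoTab <- stage("logo", {
    cols <- projectToReference(filtered, sim$reference)
    grp <- truth$abbreviation[match(rownames(cols), truth$id)]
    logoForPositions(columns = cols, positions = config$logoPositions,
                     groups = grp,
                     smallSampleCorrection = config$smallSampleCorrection)
  })
  writeTsv(logoTab, out("logo.tsv"))

  writeLines(pipelineSummary(phyletic, cls, config), out("summary.txt"))
  cfgCopy <- unclass(config)
  cfgCopy$outputDir <- NULL  # extrinsic to the run's scientific content
  jsonlite::write_json(cfgCopy, out("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c("queries.fasta", "truth.tsv", "annotation.tsv",
             "classification.tsv", "phyletic.json", "phyletic_table.tsv",
             "tree.nwk", "logo.tsv", "summary.txt", "config.json")
  invisible(list(simulation = sim, annotation = ann, classification = cls,
                 phyletic = phyletic, tree = treeFit, logo = logoTab,
                 paths = vapply(paths, out, character(1))))
}

pipelineSummary <- function(phyletic, cls, config) {
  hot <- phyletic$subfamily_shares[
    phyletic$subfamily_shares$subfamily == "cd08190", , drop = FALSE]
  lines <- c(
    "FeADH synthetic-study summary",
    sprintf("seed: %d", config$seed),
    sprintf("queries classified: %d (assigned %d, divergent %d, excluded %d)",
            nrow(cls), sum(cls$status == "assigned"),
            sum(cls$status == "divergent_unassigned"),
            sum(cls$status == "excluded_gdh_like")),
    sprintf("eukaryote assignments: %d", phyletic$eukaryote_total))
  if (nrow(hot) == 1L && phyletic$eukaryote_total > 0)
    lines <- c(lines, sprintf(
      "HOT share of eukaryote assignments: %s (%.1f%%)",
      formatPercent(hot$n_eukaryote, phyletic$eukaryote_total),
      hot$share_exact))
  if (phyletic$animal_hot$total > 0)
    lines <- c(lines, sprintf(
      "HOT share of animal assignments: %s (%.1f%%)",
      formatPercent(phyletic$animal_hot$n, phyletic$animal_hot$total),
      phyletic$animal_hot$share_exact))
  if (phyletic$fungi_hot$total > 0)
    lines <- c(lines, sprintf(
      "HOT share of fungal assignments: %s (%.1f%%)",
      formatPercent(phyletic$fungi_hot$n, phyletic$fungi_hot$total),
      phyletic$fungi_hot$share_exact))
  lines
}

#' Render a phyletic table as TSV
#'
#' Lays the counts out with one row per taxon group, one column per
#' subfamily, integer cells and a totals row.
#'
#' @param table A `"PhyleticTable"` from [summarizePhyletic()].
#' @param path Optional output file.
#' @return The rendered `data.frame` (invisibly when `path` is given).
#' @export
renderPhyleticTable <- function(table, path = NULL) {
  counts <- t(table$counts)
  df <- as.data.frame(counts, stringsAsFactors = FALSE)
  df <- cbind(taxon_group = rownames(counts), df)
  rownames(df) <- NULL
  if (nrow(df)) {
    totals <- c(taxon_group = "total",
                as.list(colSums(counts)))
    df <- rbind(df, as.data.frame(totals, check.names = FALSE))
  }
  if (!is.null(path)) {
    writeTsv(df, path)
    return(invisible(df))
  }
  df
}
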