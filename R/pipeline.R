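## End-to-end orchestration: simulate -> trim -> fit-background -> enrich
## -> posbias -> report, from a single validated YAML config with one
## master seed.

CONFIG_KEYS <- c("design", "rounds", "reads_per_round", "order", "k",
                 "pseudocount", "strands", "max_mismatch", "motif",
                 "seed", "out_dir")

#' Validate a pipeline configuration file
#'
#' YAML with keys `design` (path to a design file, required), `out_dir`
#' (required), and optional `rounds` (default 3), `reads_per_round`
#' (default 200000), `order` (default 5), `k` (default 16), `pseudocount`
#' (default 0.5), `strands` (default `forward_only`), `max_mismatch`
#' (default 2), `motif` (optimal motif of the simulation model; default:
#' the built-in DUX4 CT-optimal model), `seed` (default 1).  Validation is
#' strict: unknown keys are errors, and every problem is reported, not
#' just the first.
#'
#' @param path path to the YAML config.
#' @return a [RunConfig-class]; on any problem an error listing all
#'   validation failures.
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errors <- character()
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown)) {
    errors <- c(errors, paste("unknown config key(s):",
                              paste(unknown, collapse = ", ")))
  }
  getNum <- function(key, default) {
    v <- if (key %in% names(cfg)) cfg[[key]] else default
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      errors <<- c(errors, paste0("'", key, "' must be a single number"))
      default
    } else {
      v
    }
  }
  design <- cfg[["design"]]
  if (is.null(design)) {
    errors <- c(errors, "'design' is required")
    design <- NA_character_
  } else if (!file.exists(design)) {
    errors <- c(errors, paste("design file does not exist:", design))
  }
  outDir <- cfg[["out_dir"]]
  if (is.null(outDir)) {
    errors <- c(errors, "'out_dir' is required")
    outDir <- NA_character_
  }
  rounds <- getNum("rounds", 3)
  if (!is.na(rounds) && rounds < 0) {
    errors <- c(errors, "rounds must be >= 0")
  }
  readsPerRound <- getNum("reads_per_round", 200000)
  if (readsPerRound <= 0) errors <- c(errors, "reads_per_round must be > 0")
  order <- getNum("order", 5)
  if (order < 0) errors <- c(errors, "order must be >= 0")
  k <- getNum("k", 16)
  if (k < 1) errors <- c(errors, "k must be >= 1")
  pseudocount <- getNum("pseudocount", 0.5)
  if (pseudocount < 0) errors <- c(errors, "pseudocount must be >= 0")
  maxMismatch <- getNum("max_mismatch", 2)
  if (maxMismatch < 0) errors <- c(errors, "max_mismatch must be >= 0")
  seed <- getNum("seed", 1)
  strands <- if ("strands" %in% names(cfg)) cfg[["strands"]] else "forward_only"
  if (!strands %in% c("forward_only", "both")) {
    errors <- c(errors, "strands must be 'forward_only' or 'both'")
  }
  motif <- if ("motif" %in% names(cfg)) toupper(cfg[["motif"]]) else NA_character_
  if (!is.na(motif) && !grepl("^[ACGT]+$", motif)) {
    errors <- c(errors, "motif must be an ACGT string")
  }
  if (length(errors)) {
    stop("invalid config:\n  - ", paste(errors, collapse = "\n  - "))
  }
  new("RunConfig",
      designPath = design, rounds = as.integer(rounds),
      readsPerRound = as.integer(readsPerRound), order = as.integer(order),
      k = as.integer(k), pseudocount = pseudocount, strands = strands,
      maxMismatch = as.integer(maxMismatch), motif = motif,
      seed = as.integer(seed), outDir = outDir)
}

configHash <- function(config) {
  canon <- paste(
    config@designPath, config@rounds, config@readsPerRound, config@order,
    config@k, config@pseudocount, config@strands, config@maxMismatch,
    config@motif, config@seed, sep = "|"
  )
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

outputHeader <- function(config) {
  sprintf("selexr %s seed=%d config=%s",
          as.character(utils::packageVersion("selexr")),
          config@seed, configHash(config))
}

pipelineModel <- function(config, design) {
  if (!is.na(config@motif)) {
    return(plantedBindingModel(config@motif, strands = config@strands))
  }
  core <- coreIndex(design)
  flanked <- length(core) == 11L && min(core) > 3L &&
    max(core) <= variableLength(design) - 3L
  defaultBindingModel(flanks = flanked, strands = config@strands)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured experiment, trims adapters, fits the Markov
#' background on the round-0 control, calls enriched k-mers in the final
#' round, computes the positional selection-bias matrix, calls the
#' consensus, scores the band-shift oligo panel with the derived weight
#' matrix, and writes a plain-text report plus per-stage TSVs.  Every
#' tabular output starts with a header line recording the tool version,
#' seed and config hash; identical config and seed give a byte-identical
#' report.
#'
#' @param config a [RunConfig-class] from [validateConfig()].
#' @param verbose log stage progress to stderr.
#' @return invisibly, a list with `report` (path), `consensus` (the
#'   called consensus string or `NA`), `topEnriched`, `oligoRanking`,
#'   `bias` and `summary`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  hdr <- outputHeader(config)
  outDir <- config@outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  log <- function(...) if (verbose) message(...)

  design <- stage("design", readDesign(config@designPath))
  model <- pipelineModel(config, design)

  log("simulate: ", config@rounds, " round(s) x ", config@readsPerRound,
      " reads")
  sim <- stage("simulate", runExperiment(
    SelexExperiment(design, config@rounds, config@readsPerRound,
                    seed = config@seed),
    model, outDir, verbose = verbose
  ))

  log("trim: anchored adapter extraction")
  roundRegions <- stage("trim", lapply(sim$files, function(f) {
    reads <- parseReads(f, format = "fastq")
    trimmed <- extractVariableRegions(reads, design, config@maxMismatch)
    rc <- regionCounts(trimmed$accepted)
    out <- sub("\\.fastq$", ".regions.tsv", f)
    writeRegionCounts(rc, out, header = hdr)
    rc
  }))

  log("fit-background: order ", config@order)
  background <- stage("fit-background", fitMarkov(
    roundRegions[[1L]], order = config@order,
    pseudocount = config@pseudocount
  ))
  writeMarkovModel(background, file.path(outDir, "background.tsv"),
                   header = hdr)

  enriched <- NULL
  bias <- NULL
  consensus <- NA_character_
  oligoRanking <- NULL
  if (config@rounds >= 1L) {
    log("enrich: k = ", config@k)
    final <- roundRegions[[config@rounds + 1L]]
    enriched <- stage("enrich", {
      obs <- countKmers(final, config@k, strands = config@strands)
      nWin <- sum((nchar(final$region) - config@k + 1L) * final$count) *
        if (config@strands == "both") 2L else 1L
      expd <- expectedKmerCounts(background, config@k, nWin,
                                 regionLength = variableLength(design),
                                 kmers = names(obs))
      e <- enrichKmers(obs, expd, rounds = config@rounds)
      if (config@k >= 11L) {
        mc <- matchConsensus(e$kmer, strands = config@strands)
        e$consensus_match <- mc$match
        e$flavor <- mc$flavor
      }
      e
    })
    enrichPath <- file.path(outDir, "enrichment.tsv")
    con <- file(enrichPath, "w")
    writeLines(paste("#", hdr), con)
    utils::write.table(as.data.frame(enriched), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)

    log("posbias: selected round ", config@rounds, " vs control")
    bias <- stage("posbias", selectionBias(
      baseFrequencyMatrix(roundRegions[[config@rounds + 1L]], design),
      baseFrequencyMatrix(roundRegions[[1L]], design),
      design
    ))
    writeBiasTable(bias, file.path(outDir, "bias.tsv"), header = hdr)
    call <- callConsensus(bias)
    consensus <- call$consensus
    oligoRanking <- stage("oligo-panel", scoreOligoPanel(
      biasWeightMatrix(bias), dux4OligoPanel(), strands = config@strands
    ))
  }

  report <- file.path(outDir, "report.txt")
  con <- file(report, "w")
  writeLines(paste("#", hdr), con)
  writeLines("", con)
  writeLines("== Run summary ==", con)
  utils::write.table(format(sim$summary, digits = 6), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines("", con)
  if (config@rounds < 1L) {
    writeLines("no selection; enrichment skipped", con)
  } else {
    writeLines("== Top 20 enriched k-mers ==", con)
    top <- utils::head(as.data.frame(enriched), 20L)
    utils::write.table(format(top, digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines("", con)
    writeLines("== Positional selection bias (ratio) ==", con)
    r <- format(round(biasRatios(bias), 4L), trim = TRUE)
    utils::write.table(cbind(base = DNA_BASES, r), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines("", con)
    writeLines(paste("== Called consensus ==", consensus), con)
    writeLines("", con)
    writeLines("== Oligo panel ranking ==", con)
    utils::write.table(format(as.data.frame(oligoRanking), digits = 6),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  close(con)
  log("report: ", report)
  invisible(list(report = report, consensus = consensus,
                 topEnriched = enriched, oligoRanking = oligoRanking,
                 bias = bias, summary = sim$summary))
}

#' @rdname RunConfig-class
#' @param object object to display
#' @export
setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: design ", object@designPath, ", ", object@rounds,
      " round(s) x ", object@readsPerRound, " reads, order ",
      object@order, ", k ", object@k, ", seed ", object@seed, "\n",
      sep = "")
})
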