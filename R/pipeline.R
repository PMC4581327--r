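#' @include AllClasses.R clusters.R scanners.R annotations.R ptm-stats.R synthetic.R
NULL

.PARAMETERS <- c("phospho_S", "phospho_T", "phospho_Y", "ogly", "ngly",
                 "ubiquitination", "pest", "tm_helix")
.SITE_PARAMS <- c("phospho_S", "phospho_T", "phospho_Y", "ogly", "ngly",
                  "ubiquitination")

#' Subset an annotated proteome to a set of proteins
#'
#' @param ap an [AnnotatedProteome-class].
#' @param ids protein ids to keep (input order of the proteome preserved).
#' @return an [AnnotatedProteome-class] restricted to `ids`.
#' @export
subsetProteins <- function(ap, ids) {
  keep <- proteinIds(ap) %in% ids
  out <- ap
  out@sequences <- ap@sequences[keep]
  out@descriptions <- ap@descriptions[keep]
  kept <- names(out@sequences)
  out@masks <- ap@masks[kept]
  out@sites <- ap@sites[ap@sites$protein_id %in% kept, , drop = FALSE]
  out@segments <- ap@segments[ap@segments$protein_id %in% kept, ,
                              drop = FALSE]
  rownames(out@sites) <- NULL
  rownames(out@segments) <- NULL
  out
}

#' Assemble a pipeline run configuration
#'
#' A declarative description of one full analysis run. Input is either a
#' [synthConfig()] (`synth =`) or a list of species entries
#' (`species = list(list(speciesId =, group =, fasta =, sites =, masks =,
#' segments =, maskFormat = "binary"))`). All analysis options ambiguous in
#' the underlying study surface here with documented defaults.
#'
#' @param synth optional [synthConfig()] for synthetic input.
#' @param species optional list of species file entries (see above).
#' @param lengthFilter list `min`, `max` (residues); default 50/4000.
#' @param redundancy list `enable`, `piCutoff`, `pmatchCutoff` for the
#'   90/90 redundancy clustering and representative selection.
#' @param categories list `source` (`"clusters"`, `"external"` or
#'   `"truth"`), `piCutoff`/`pmatchCutoff` of the looser family clustering
#'   used for the specific/common classification, `externalPath` for a
#'   cluster TSV, and `onFiltered` (classify on the redundancy-filtered set,
#'   the default, or on the raw set).
#' @param scanners list `oglyOverlap`, `oglyExtent`, `nglyGate`,
#'   `excludeSignalRegion`, `pestThreshold`, `ubLow`, `ubHigh`.
#' @param stats list `cap` (bin cap K), `fdrFamily` (`"species"` or
#'   `"global"`), `densityMode` (`"pooled"` or `"mean"`).
#' @param seed integer seed for any resampling inside the run.
#' @param outDir optional directory; when set, [runPipeline()] persists all
#'   intermediate tables there.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(synth = NULL, species = NULL,
                      lengthFilter = list(min = 50L, max = 4000L),
                      redundancy = list(enable = TRUE, piCutoff = 90,
                                        pmatchCutoff = 90),
                      categories = list(source = "clusters", piCutoff = 50,
                                        pmatchCutoff = 50,
                                        externalPath = NULL,
                                        onFiltered = TRUE),
                      scanners = list(oglyOverlap = "none",
                                      oglyExtent = "shortest",
                                      nglyGate = "signal_or_tm",
                                      excludeSignalRegion = TRUE,
                                      pestThreshold = 5.0,
                                      ubLow = 0.69, ubHigh = 0.84),
                      stats = list(cap = 7L, fdrFamily = "species",
                                   densityMode = "pooled"),
                      seed = 1L, outDir = NULL) {
  if (is.null(synth) && is.null(species))
    stop("config must provide either 'synth' or 'species' input")
  if (!is.null(species)) {
    for (sp in species) {
      for (f in c("fasta", "sites", "masks", "segments")) {
        if (!is.null(sp[[f]]) && !file.exists(sp[[f]]))
          stop("input file for species ", sp$speciesId, " not found: ",
               sp[[f]])
      }
    }
  }
  structure(list(synth = synth, species = species,
                 lengthFilter = lengthFilter, redundancy = redundancy,
                 categories = categories, scanners = scanners,
                 stats = stats, seed = as.integer(seed), outDir = outDir),
            class = "runConfig")
}

#' Load a pipeline configuration from a YAML file
#'
#' File keys mirror the arguments of [runConfig()]; a `synth` block is
#' passed to [synthConfig()]. Relative paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file.
#' @return a `runConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  if (!is.null(y$species)) {
    y$species <- lapply(y$species, function(sp) {
      for (f in c("fasta", "sites", "masks", "segments"))
        if (!is.null(sp[[f]]) && !grepl("^/", sp[[f]]))
          sp[[f]] <- file.path(base, sp[[f]])
      sp
    })
  }
  if (!is.null(y$synth)) y$synth <- do.call(synthConfig, y$synth)
  args <- y[intersect(names(y), names(formals(runConfig)))]
  defaults <- formals(runConfig)
  for (nm in c("lengthFilter", "redundancy", "categories", "scanners",
               "stats")) {
    if (!is.null(args[[nm]])) {
      d <- eval(defaults[[nm]])
      d[names(args[[nm]])] <- args[[nm]]
      args[[nm]] <- d
    }
  }
  do.call(runConfig, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.loadInputs <- function(config) {
  if (!is.null(config$synth)) {
    gen <- generateProteomes(config$synth)
    list(proteomes = gen$proteomes, truth = gen$truthProteins)
  } else {
    prot <- lapply(config$species, function(sp) {
      p <- readProteomeFasta(sp$fasta, sp$speciesId,
                             group = if (is.null(sp$group)) "other"
                             else sp$group)
      masks <- readDisorderMasks(sp$masks, p,
                                 format = if (is.null(sp$maskFormat))
                                   "binary" else sp$maskFormat)
      sites <- if (is.null(sp$sites)) NULL else readSiteTable(sp$sites, p)
      segs <- if (is.null(sp$segments)) NULL
              else readSegmentTable(sp$segments, p)
      annotateProteome(p, masks, sites, segs)
    })
    names(prot) <- vapply(config$species, `[[`, character(1), "speciesId")
    list(proteomes = prot, truth = NULL)
  }
}

# Per-protein counts and countable site anchors for all 8 parameters.
.scanSpecies <- function(ap, sc) {
  ids <- proteinIds(ap)
  seqs <- as.character(aaSequences(ap))
  segs <- segmentTable(ap)
  sites <- filterUbiquitination(siteTable(ap), low = sc$ubLow,
                                high = sc$ubHigh, strict = FALSE)
  counts <- matrix(0L, length(ids), length(.PARAMETERS),
                   dimnames = list(ids, .PARAMETERS))
  anchors <- list()
  for (ty in c("phospho_S", "phospho_T", "phospho_Y", "ubiquitination")) {
    st <- sites[sites$site_type == ty, , drop = FALSE]
    if (nrow(st)) {
      tab <- table(st$protein_id)
      counts[names(tab), ty] <- as.integer(tab)
    }
    anchors[[ty]] <- data.frame(protein_id = st$protein_id,
                                position = st$position,
                                stringsAsFactors = FALSE)
  }
  og <- lapply(ids, function(i)
    scanOgly(seqs[[i]], i, overlap = sc$oglyOverlap,
             extent = sc$oglyExtent))
  og <- do.call(rbind, og)
  ng <- lapply(ids, function(i)
    combineNgly(scanNglySequons(seqs[[i]], i), secretoryContextFor(segs, i),
                gate = sc$nglyGate,
                excludeSignalRegion = sc$excludeSignalRegion))
  ng <- do.call(rbind, ng)
  pe <- do.call(rbind, lapply(ids, function(i)
    scanPest(seqs[[i]], i, threshold = sc$pestThreshold)))
  for (d in list(list("ogly", og), list("ngly", ng), list("pest", pe))) {
    ty <- d[[1]]; m <- d[[2]]
    if (!is.null(m) && nrow(m)) {
      tab <- table(m$protein_id)
      counts[names(tab), ty] <- as.integer(tab)
    }
    anchors[[ty]] <- if (is.null(m) || !nrow(m))
      data.frame(protein_id = character(), position = integer())
    else data.frame(protein_id = m$protein_id, position = m$anchor,
                    stringsAsFactors = FALSE)
  }
  tm <- segs[segs$segment_type == "tm_helix", , drop = FALSE]
  if (nrow(tm)) {
    tab <- table(tm$protein_id)
    counts[intersect(names(tab), ids), "tm_helix"] <-
      as.integer(tab[intersect(names(tab), ids)])
  }
  matches <- rbind(og, ng, pe)
  list(counts = counts, anchors = anchors, matches = matches)
}

#' Run the full disorder/PTM analysis pipeline
#'
#' Executes the stages in analysis order — ingest (or simulate), length
#' filter, redundancy clustering and representative selection, sequence
#' scanning and annotation joining, per-400 densities, site-count binning
#' with one-tailed Pearson inference and BH FDR, Rd/o per species and per
#' group, and the species-specific vs common cluster contrast — and returns
#' a structured report. Reruns with an identical config are identical.
#'
#' @param config a `runConfig` from [runConfig()] or [readRunConfig()].
#' @return list of class `ptmRunReport` with `speciesSummary`, `binSeries`,
#'   `table1` (r/p/FDR grid), `table2` (Rd/o per group + Total), `table3`
#'   (specific/common contrast), `densities`, and `provenance`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  set.seed(config$seed)
  inputs <- .stage("ingest", .loadInputs(config))
  proteomes <- inputs$proteomes
  panel <- names(proteomes)

  n_before <- vapply(proteomes, nProteins, integer(1))
  proteomes <- .stage("length_filter", lapply(
    proteomes, filterByLength,
    minLen = config$lengthFilter$min, maxLen = config$lengthFilter$max))
  n_filtered <- vapply(proteomes, nProteins, integer(1))

  reps_info <- NULL
  raw_proteomes <- proteomes
  if (isTRUE(config$redundancy$enable)) {
    catalog <- .stage("redundancy_clustering", buildClusters(
      proteomes, identityParams(config$redundancy$piCutoff,
                                config$redundancy$pmatchCutoff)))
    reps <- selectRepresentatives(catalog, proteomes)
    proteomes <- lapply(proteomes, function(ap)
      subsetProteins(ap, reps$protein_id[reps$species_id == speciesId(ap)]))
    reps_info <- list(catalog = catalog, representatives = reps)
  }
  n_after <- vapply(proteomes, nProteins, integer(1))

  scans <- .stage("scan", lapply(proteomes, .scanSpecies, sc = config$scanners))

  # per-species statistics
  cap <- config$stats$cap
  table1 <- list(); bin_series <- list(); dens <- list(); rdo_rows <- list()
  summary_rows <- list()
  for (sp in panel) {
    ap <- proteomes[[sp]]
    sc <- scans[[sp]]
    masks <- disorderMasks(ap)
    dc <- disorderContent(masks)
    lens <- Biostrings::width(aaSequences(ap))
    rows <- list()
    for (par in .PARAMETERS) {
      cnt <- sc$counts[, par]
      series <- binBySiteCount(cnt, dc, cap = cap, parameter = par)
      bin_series[[paste(sp, par, sep = ".")]] <-
        data.frame(species_id = sp, parameter = par, series,
                   stringsAsFactors = FALSE)
      pr <- if (isTRUE(attr(series, "correlation_ok")) &&
                stats::sd(series$mean_disorder) > 0)
        pearsonOneTailed(series)
      else list(r = NA_real_, n = nrow(series), p_one_tailed = NA_real_,
                direction = NA_character_)
      d400 <- if (identical(config$stats$densityMode, "pooled"))
        pooledDensityPer400(cnt, lens)
      else mean(densityPer400(cnt, lens))
      rows[[par]] <- data.frame(species_id = sp, parameter = par,
                                r = pr$r, n_bins = pr$n,
                                p_one_tailed = pr$p_one_tailed,
                                stringsAsFactors = FALSE)
      dens[[paste(sp, par, sep = ".")]] <-
        data.frame(species_id = sp, parameter = par, density_per_400 = d400,
                   stringsAsFactors = FALSE)
    }
    t1 <- do.call(rbind, rows)
    if (identical(config$stats$fdrFamily, "species")) {
      ok <- !is.na(t1$p_one_tailed)
      t1$fdr <- NA_real_
      if (any(ok)) t1$fdr[ok] <- bhFdr(t1$p_one_tailed[ok])
    }
    table1[[sp]] <- t1
    for (par in .SITE_PARAMS) {
      res <- rdo(sc$anchors[[par]], masks)
      rdo_rows[[paste(sp, par, sep = ".")]] <-
        data.frame(species_id = sp, parameter = par, Nd = res$Nd,
                   Ld = res$Ld, No = res$No, Lo = res$Lo, rdo = res$rdo,
                   stringsAsFactors = FALSE)
    }
    summary_rows[[sp]] <- data.frame(
      species_id = sp, group = speciesGroup(ap),
      n_input = n_before[[sp]], n_length_filtered = n_filtered[[sp]],
      n_nonredundant = n_after[[sp]],
      redundancy_content = redundancyContent(n_filtered[[sp]], n_after[[sp]]),
      mean_disorder = mean(dc), total_aa = totalAA(ap),
      stringsAsFactors = FALSE)
  }
  table1 <- do.call(rbind, table1)
  rownames(table1) <- NULL
  if (identical(config$stats$fdrFamily, "global")) {
    ok <- !is.na(table1$p_one_tailed)
    table1$fdr <- NA_real_
    table1$fdr[ok] <- bhFdr(table1$p_one_tailed[ok])
  }

  rdo_tab <- do.call(rbind, rdo_rows)
  rownames(rdo_tab) <- NULL
  grouping <- vapply(proteomes, speciesGroup, character(1))
  table2 <- do.call(rbind, lapply(.SITE_PARAMS, function(par) {
    d <- rdo_tab[rdo_tab$parameter == par, , drop = FALSE]
    out <- groupAggregateRdo(d[c("species_id", "Nd", "Ld", "No", "Lo")],
                             grouping)
    data.frame(parameter = par, out, stringsAsFactors = FALSE)
  }))
  rownames(table2) <- NULL

  table3 <- .stage("category_contrast",
                   .contrastStage(config, proteomes, raw_proteomes, scans,
                                  inputs$truth, panel))

  report <- structure(list(
    speciesSummary = do.call(rbind, c(summary_rows,
                                      list(make.row.names = FALSE))),
    binSeries = do.call(rbind, c(bin_series, list(make.row.names = FALSE))),
    densities = do.call(rbind, c(dens, list(make.row.names = FALSE))),
    table1 = table1, rdoPerSpecies = rdo_tab, table2 = table2,
    table3 = table3,
    representatives = reps_info$representatives,
    provenance = list(configHash = .hashConfig(config),
                      package = as.character(utils::packageVersion("idrptm")),
                      seed = config$seed)),
    class = "ptmRunReport")
  if (!is.null(config$outDir)) writeReportTables(report, config$outDir)
  report
}

.contrastStage <- function(config, proteomes, raw_proteomes, scans, truth,
                           panel) {
  cc <- config$categories
  base <- if (isTRUE(cc$onFiltered)) proteomes else raw_proteomes
  catalog <- switch(
    cc$source,
    clusters = buildClusters(base, identityParams(cc$piCutoff,
                                                  cc$pmatchCutoff)),
    external = readClusterTable(cc$externalPath),
    truth = {
      if (is.null(truth)) stop("no ground truth available for categories")
      keep <- paste(truth$species_id, truth$protein_id) %in%
        unlist(lapply(base, function(ap)
          paste(speciesId(ap), proteinIds(ap))))
      new("ClusterCatalog",
          assignments = data.frame(cluster_id = truth$family_id[keep],
                                   species_id = truth$species_id[keep],
                                   protein_id = truth$protein_id[keep],
                                   stringsAsFactors = FALSE))
    },
    stop("unknown category source: ", cc$source))
  cats <- classifyClusters(catalog, panel)
  cat_by_cluster <- stats::setNames(cats$category, cats$cluster_id)
  a <- clusterTable(catalog)
  a$category <- unname(cat_by_cluster[a$cluster_id])
  key <- stats::setNames(a$category, paste(a$species_id, a$protein_id))

  rows <- list()
  metrics <- c("disorder", .SITE_PARAMS)
  vals <- list(); catv <- list()
  for (sp in names(base)) {
    ap <- base[[sp]]
    ids <- proteinIds(ap)
    category <- unname(key[paste(sp, ids)])
    dc <- disorderContent(disorderMasks(ap))
    lens <- Biostrings::width(aaSequences(ap))
    cnts <- if (sp %in% names(scans)) scans[[sp]]$counts else NULL
    for (m in metrics) {
      v <- if (m == "disorder") dc
      else if (!is.null(cnts) && all(ids %in% rownames(cnts)))
        densityPer400(cnts[ids, m], lens)
      else rep(NA_real_, length(ids))
      vals[[m]] <- c(vals[[m]], v)
      catv[[m]] <- c(catv[[m]], category)
    }
  }
  for (m in metrics) {
    ok <- !is.na(vals[[m]]) & catv[[m]] %in% c("specific", "common")
    if (!any(catv[[m]][ok] == "specific") ||
        !any(catv[[m]][ok] == "common")) next
    res <- categoryContrast(vals[[m]][ok], catv[[m]][ok])
    rows[[m]] <- data.frame(metric = m, mean_specific = res$mean_specific,
                            mean_common = res$mean_common,
                            ratio_s_over_c = res$ratio_s_over_c,
                            p_one_tailed = res$p_one_tailed,
                            n_specific = res$n_specific,
                            n_common = res$n_common,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

.hashConfig <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (x in utf8ToInt(s)) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", h)
}

#' One-significant-figure scientific display of p values
#'
#' Formats like the compact table display `2e-05` while full-precision
#' values stay in the numeric columns.
#'
#' @param p numeric vector.
#' @return character vector.
#' @examples
#' formatSignif1(1.7e-5)  # "2e-05"
#' @export
formatSignif1 <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.0e", signif(p, 1)))
}

#' @export
print.ptmRunReport <- function(x, ...) {
  cat("Disorder/PTM pipeline report\n")
  cat("  species:", nrow(x$speciesSummary), "| parameters:",
      length(unique(x$table1$parameter)), "\n")
  cat("  config hash:", x$provenance$configHash, "\n")
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Persists `species_summary.tsv`, `bin_series.tsv`, `densities.tsv`,
#' `table1.tsv` (with one-significant-figure display columns alongside the
#' full-precision p/FDR columns), `rdo_per_species.tsv`, `table2.tsv` and
#' `table3.tsv` in fixed column order.
#'
#' @param report a `ptmRunReport`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeReportTables <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    if (is.null(d) || !nrow(d))
      warning("empty table: ", f, call. = FALSE)
    utils::write.table(d, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  t1 <- report$table1
  t1$p_display <- formatSignif1(t1$p_one_tailed)
  t1$fdr_display <- formatSignif1(t1$fdr)
  wt(report$speciesSummary, "species_summary.tsv")
  wt(report$binSeries, "bin_series.tsv")
  wt(report$densities, "densities.tsv")
  wt(t1, "table1.tsv")
  wt(report$rdoPerSpecies, "rdo_per_species.tsv")
  wt(report$table2, "table2.tsv")
  t3 <- report$table3
  if (!is.null(t3)) t3$p_display <- formatSignif1(t3$p_one_tailed)
  wt(t3, "table3.tsv")
  invisible(outdir)
}
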