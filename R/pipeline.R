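#' Validate a pipeline run configuration
#'
#' A RunConfig is a declarative list (usually read from JSON): a global
#' `seed`, an `out_dir`, and a `stages` block. Each requested stage names
#' exactly one input source — file paths, or `"synthetic": true` to consume
#' what the `simulate` stage generated. Defaults for every tunable mirror
#' the package's documented defaults.
#'
#' @param config list or path to a JSON file
#' @return the normalized config list (class `run_config`)
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  if (is.null(config$out_dir)) stop("config field missing: out_dir")
  if (is.null(config$seed)) stop("config field missing: seed")
  if (is.null(config$stages) || !length(config$stages))
    stop("config field missing: stages")

  known <- c("simulate", "ggd", "cogmap", "contrasts", "rrna", "stats")
  bad <- setdiff(names(config$stages), known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  needs_sim <- function(st) isTRUE(st$synthetic)
  for (nm in setdiff(names(config$stages), "simulate")) {
    st <- config$stages[[nm]]
    req <- switch(nm,
                  ggd = c("a", "b"),
                  cogmap = "tables",
                  contrasts = c("tree", "traits"),
                  rrna = c("hits", "annot", "query_length"),
                  stats = "genome")
    if (needs_sim(st)) {
      if (is.null(config$stages$simulate))
        stop("stage '", nm, "' requests synthetic input but there is no ",
             "simulate stage")
      next
    }
    miss <- req[vapply(req, function(f) is.null(st[[f]]), TRUE)]
    if (length(miss))
      stop("stage '", nm, "' config field missing: ",
           paste(miss, collapse = ", "),
           " (provide the path(s) or set synthetic: true)")
  }
  structure(config, class = c("run_config", "list"))
}

#' Run the pipeline end-to-end
#'
#' Executes the configured stages in order (simulate, ggd, cogmap,
#' contrasts, rrna, stats), writing each stage's outputs under
#' `out_dir/<stage>/`. The run is deterministic given the seed and inputs;
#' a manifest listing every output file with its MD5 digest, plus the seed,
#' is written to `out_dir/manifest.json`. On stage failure, completed
#' stages' outputs are left intact and the error names the failing stage.
#'
#' @param config list or JSON path (see [validate_config()])
#' @return the manifest data.frame, invisibly
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  # independent, reproducible per-stage seeds derived from the global one
  stage_seed <- setNames(sample.int(.Machine$integer.max %/% 2, 6),
                         c("simulate", "ggd", "cogmap", "contrasts",
                           "rrna", "stats"))
  sim <- NULL
  outputs <- character(0)

  run_stage <- function(name, fun) {
    if (is.null(config$stages[[name]])) return(invisible(NULL))
    message("[spirotax] stage ", name, " (seed ", stage_seed[[name]], ")")
    dir.create(file.path(out_dir, name), showWarnings = FALSE)
    tryCatch(fun(config$stages[[name]]),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  default <- function(st, field, value) {
    if (is.null(st[[field]])) value else st[[field]]
  }

  ## ---- simulate -----------------------------------------------------
  run_stage("simulate", function(st) {
    set.seed(stage_seed[["simulate"]])
    sdir <- file.path(out_dir, "simulate")
    pair <- simulate_genome_pair(genome_pair_spec(
      ancestor_length = default(st, "ancestor_length", 50000L),
      alignable_fraction = default(st, "alignable_fraction", 0.30),
      within_identity = default(st, "within_identity", 0.85),
      n_segments = default(st, "n_segments", 10L)))
    write_genome_fasta(pair$genome_a, file.path(sdir, "genome_a.fna"))
    write_genome_fasta(pair$genome_b, file.path(sdir, "genome_b.fna"))
    write_truth_map(pair$truth, file.path(sdir, "truth.bed"))

    tree <- simulate_tree(default(st, "n_taxa", 32L),
                          default(st, "birth_rate", 1))
    ape::write.tree(tree, file.path(sdir, "tree.nwk"))
    traits <- simulate_correlated_traits(tree, trait_sim_spec(
      rho = default(st, "rho", 0.8)))
    write_trait_table(traits, file.path(sdir, "traits.tsv"))

    groups <- default(st, "groups", c("free_living", "host_associated"))
    n_genomes <- default(st, "genomes_per_group", 4L)
    profiles <- setNames(lapply(groups, function(g) random_cog_profile(2)),
                         groups)
    spec <- cog_profile_spec(profiles)
    for (g in groups) for (i in seq_len(n_genomes)) {
      tab <- simulate_cog_table(spec, g)
      write_tsv_matrix(tab, file.path(sdir, sprintf("%s_%d.genes.tsv", g, i)))
    }
    sim <<- list(dir = sdir, pair = pair, tree = tree, traits = traits)
    outputs <<- c(outputs, list.files(sdir, full.names = TRUE))
  })

  ## ---- genome distance ----------------------------------------------
  run_stage("ggd", function(st) {
    gdir <- file.path(out_dir, "ggd")
    if (isTRUE(st$synthetic)) {
      ga <- sim$pair$genome_a; gb <- sim$pair$genome_b
    } else {
      ga <- read_genome_fasta(st$a); gb <- read_genome_fasta(st$b)
    }
    hsps <- find_hsps(ga, gb,
                      word_size = default(st, "word_size", 11L),
                      min_score = default(st, "min_score", 28L),
                      x_drop = default(st, "x_drop", 20L))
    triple <- compute_distance_formulas(hsps)
    write_hsp_table(hsps, file.path(gdir, "hsps.tsv"))
    write.table(ggd_report_row(triple, ga$id, gb$id),
                file.path(gdir, "report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs <<- c(outputs, file.path(gdir, c("hsps.tsv", "report.tsv")))
  })

  ## ---- COG heatmap ---------------------------------------------------
  run_stage("cogmap", function(st) {
    cdir <- file.path(out_dir, "cogmap")
    tdir <- if (isTRUE(st$synthetic)) file.path(out_dir, "simulate")
            else st$tables
    files <- list.files(tdir, pattern = "\\.genes\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no *.genes.tsv tables found in ", tdir)
    counts <- lapply(files, function(f) count_categories(read_gene_table(f)))
    names(counts) <- sub("\\.genes\\.tsv$", "", basename(files))
    m <- cog_count_matrix(counts)
    tm <- transform_cog_matrix(m, default(st, "transform", "arcsine_sqrt"))
    cl <- cluster_heatmap(tm, file = file.path(cdir, "heatmap.svg"))
    write_tsv_matrix(m, file.path(cdir, "counts.tsv"))
    write_tsv_matrix(tm, file.path(cdir, "transformed.tsv"))
    writeLines(c(paste("row_order", paste(cl$row_order, collapse = ",")),
                 paste("col_order", paste(cl$col_order, collapse = ","))),
               file.path(cdir, "cluster_orders.txt"))
    outputs <<- c(outputs, file.path(cdir, c("heatmap.svg", "counts.tsv",
                                             "transformed.tsv",
                                             "cluster_orders.txt")))
  })

  ## ---- contrasts ------------------------------------------------------
  run_stage("contrasts", function(st) {
    ddir <- file.path(out_dir, "contrasts")
    if (isTRUE(st$synthetic)) {
      tree <- sim$tree; traits <- sim$traits
    } else {
      tree <- ape::read.tree(st$tree)
      traits <- read_trait_table(st$traits)
    }
    tx <- setNames(traits$trait_x, traits$label)
    ty <- setNames(traits$trait_y, traits$label)
    cx <- independent_contrasts(tree, tx)
    cy <- independent_contrasts(tree, ty)
    res <- plot_trait_contrasts(traits, tree,
                                file = file.path(ddir, "scatter.svg"))
    write_tsv_matrix(data.frame(node = cx$node, contrast_x = cx$contrast,
                                contrast_y = cy$contrast,
                                variance = cx$variance),
                     file.path(ddir, "contrasts.tsv"))
    write_tsv_matrix(data.frame(mode = c("raw", "contrasts"),
                                r = c(res$raw$r, res$contrasts$r),
                                p = c(res$raw$p, res$contrasts$p),
                                n = c(res$raw$n, res$contrasts$n)),
                     file.path(ddir, "correlations.tsv"))
    outputs <<- c(outputs, file.path(ddir, c("scatter.svg", "contrasts.tsv",
                                             "correlations.tsv")))
  })

  ## ---- 16S profile ----------------------------------------------------
  run_stage("rrna", function(st) {
    rdir <- file.path(out_dir, "rrna")
    hits <- read_hit_table(st$hits, st$annot)
    write_frequency_report(weighted_taxon_frequencies(hits),
                           file.path(rdir, "taxa.tsv"))
    write_frequency_report(weighted_keyword_frequencies(hits),
                           file.path(rdir, "keywords.tsv"))
    hs <- hsp_summary(hits, st$query_length)
    write_tsv_matrix(data.frame(mean_identity = hs$mean_identity,
                                mean_coverage = hs$mean_coverage,
                                n_hits = hs$n_hits),
                     file.path(rdir, "hsp_summary.tsv"))
    outputs <<- c(outputs, file.path(rdir, c("taxa.tsv", "keywords.tsv",
                                             "hsp_summary.tsv")))
  })

  ## ---- genome stats ---------------------------------------------------
  run_stage("stats", function(st) {
    tdir <- file.path(out_dir, "stats")
    if (grepl("\\.(gb|gbk|gbff)$", st$genome)) {
      gb <- read_genbank_features(st$genome)
      genome <- gb$genome; feats <- gb$features
    } else {
      genome <- read_genome_fasta(st$genome)
      feats <- read_feature_table(st$features)
    }
    write_tsv_matrix(genome_stats_report(genome, feats),
                     file.path(tdir, "stats.tsv"))
    outputs <<- c(outputs, file.path(tdir, "stats.tsv"))
  })

  manifest <- data.frame(file = substring(outputs, nchar(out_dir) + 2L),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(list(seed = config$seed, files = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
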