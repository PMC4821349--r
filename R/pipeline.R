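#' Run the consensus-network analysis pipeline
#'
#' Orchestrates the full workflow from one declarative configuration:
#' (1) per-species evidence from homology hits, (2) consensus gene set,
#' (3) expression-guided extraction of a consensus sub-model (GIMME and
#' iMAT, with a structural cross-check of the two), and (4) simulation
#' stages on the extracted model — single-gene deletion screening and,
#' optionally, robustness scans, a coexpression network and a knockout
#' design. Every stage logs its parameters and output files into a manifest;
#' two runs with the same configuration and seed produce identical outputs
#' and manifests (timestamps excluded).
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{model}{path to an SBML file or TSV model directory.}
#'     \item{hits}{data.frame of homology hits, or a list of
#'       `list(path, species, strategy)` entries for BLAST tables.}
#'     \item{expression}{list with `counts`, `lengths`, `samples` paths, or
#'       an `expression_matrix`.}
#'     \item{species}{species labels to intersect over; `outgroup` optional
#'       for divergence calls.}
#'     \item{evalue}{presence-call threshold (default 1e-4).}
#'     \item{extraction}{arguments for [extraction_config()].}
#'     \item{deletion_method}{"fba" (default) or "lmoma".}
#'     \item{coexpression}{list with `r_min`, `variance_filter_quantile`, or
#'       NULL to skip.}
#'     \item{design}{arguments for [design_config()], or NULL to skip.}
#'     \item{robustness_reaction}{reaction id to scan, or NULL.}
#'     \item{outdir}{output directory.}
#'     \item{seed}{integer seed for any stochastic stage.}
#'   }
#' @return the manifest (invisibly also written to `outdir/manifest.json`):
#'   a list with per-stage parameters, outputs, counts and md5 checksums.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("model", "hits", "expression", "outdir")
  missing <- setdiff(required, names(config))
  if (length(missing)) stop("pipeline config lacks: ", paste(missing, collapse = ", "))

  ## pre-flight: referenced files must exist before anything runs
  paths <- character(0)
  if (is.character(config$model)) paths <- c(paths, config$model)
  if (is.list(config$expression) && !inherits(config$expression, "expression_matrix"))
    paths <- c(paths, unlist(config$expression[c("counts", "lengths", "samples")]))
  if (is.list(config$hits) && !is.data.frame(config$hits))
    paths <- c(paths, vapply(config$hits, function(h) h$path, character(1)))
  absent <- paths[!file.exists(paths)]
  if (length(absent)) stop("pipeline inputs do not exist: ", paste(absent, collapse = ", "))

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  manifest <- list(seed = seed, stages = list())
  tsv_out <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  finish_stage <- function(name, params, outputs, counts) {
    manifest$stages[[name]] <<- list(
      parameters = params, outputs = outputs, counts = counts,
      checksums = as.list(tools::md5sum(unlist(outputs))))
  }
  fail_marker <- function(stage, e) {
    writeLines(paste0("FAILED at stage ", stage, ": ", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  }

  ## stage 1: evidence -------------------------------------------------
  stage <- "evidence"
  tryCatch({
    hits <- if (is.data.frame(config$hits)) config$hits else
      do.call(rbind, lapply(config$hits, function(h)
        read_blast_hits(h$path, h$species, h$strategy)))
    evalue <- if (is.null(config$evalue)) 1e-4 else config$evalue
    evidence <- presence_calls(hits, evalue_max = evalue, species = config$species)
    ev_df <- data.frame(gene = rownames(evidence$merged), evidence$merged,
                        check.names = FALSE)
    p1 <- tsv_out(ev_df, "evidence.tsv")
    finish_stage(stage, list(evalue = evalue), list(evidence = p1),
                 list(genes = nrow(evidence$merged),
                      present_calls = sum(evidence$merged)))
  }, error = function(e) fail_marker(stage, e))

  ## stage 2: consensus ------------------------------------------------
  stage <- "consensus"
  tryCatch({
    consensus <- consensus_gene_set(evidence, config$species)
    p2 <- file.path(outdir, "consensus_genes.txt")
    writeLines(consensus, p2)
    finish_stage(stage, list(species = config$species),
                 list(consensus_genes = p2),
                 list(consensus_genes = length(consensus)))
  }, error = function(e) fail_marker(stage, e))

  ## stage 3: extraction -----------------------------------------------
  stage <- "extraction"
  tryCatch({
    model <- if (is.character(config$model)) read_model(config$model) else config$model
    em <- if (inherits(config$expression, "expression_matrix")) config$expression else
      read_expression_tsv(config$expression$counts, config$expression$lengths,
                          config$expression$samples)
    rp <- rpkm_matrix(em)
    gene_values <- rowMeans(log2(rp + 1))
    ## measured genes without consensus evidence score 0 (below threshold);
    ## model genes never measured stay unevidenced (Inf) via gpr_value
    gene_values[setdiff(names(gene_values), consensus)] <- 0
    rexpr <- map_reaction_expression(model, gene_values)
    ex_cfg <- do.call(extraction_config,
                      if (is.null(config$extraction)) list() else config$extraction)
    gim <- extract_gimme(model, rexpr, ex_cfg)
    ima <- extract_imat(model, rexpr, ex_cfg)
    dd <- compare_models(gim, ima)
    p3 <- file.path(outdir, "consensus_model")
    write_model(gim, p3, format = "tsv")
    p3d <- file.path(outdir, "extraction_agreement.txt")
    writeLines(utils::capture.output(print(dd)), p3d)
    finish_stage(stage,
                 list(extraction = unclass(ex_cfg)),
                 list(model = file.path(p3, "reactions.tsv"), agreement = p3d),
                 list(reactions = nrow(gim$reactions),
                      metabolites = nrow(gim$metabolites),
                      genes = length(model_genes(gim)),
                      reactions_removed = nrow(model$reactions) - nrow(gim$reactions),
                      gimme_imat_equivalent = model_diff_is_empty(dd)))
    model <- gim
  }, error = function(e) fail_marker(stage, e))

  ## stage 4: simulations ----------------------------------------------
  stage <- "deletion_screen"
  tryCatch({
    method <- if (is.null(config$deletion_method)) "fba" else config$deletion_method
    screen <- single_gene_deletion_screen(model, method = method)
    p4 <- tsv_out(screen, "deletion_screen.tsv")
    finish_stage(stage, list(method = method), list(screen = p4),
                 as.list(table(screen$phenotype)))
  }, error = function(e) fail_marker(stage, e))

  if (!is.null(config$robustness_reaction)) {
    stage <- "robustness"
    tryCatch({
      rb <- robustness_scan(model, config$robustness_reaction)
      p5 <- tsv_out(rb, "robustness.tsv")
      finish_stage(stage, list(reaction = config$robustness_reaction),
                   list(scan = p5), list(points = nrow(rb)))
    }, error = function(e) fail_marker(stage, e))
  }

  if (!is.null(config$coexpression)) {
    stage <- "coexpression"
    tryCatch({
      co <- config$coexpression
      edges <- build_coexpression(
        em,
        variance_filter_quantile = if (is.null(co$variance_filter_quantile)) 0.25
                                   else co$variance_filter_quantile,
        r_min = if (is.null(co$r_min)) 0.90 else co$r_min)
      p6 <- tsv_out(edges, "coexpression_edges.tsv")
      finish_stage(stage, co, list(edges = p6), list(edges = nrow(edges)))
    }, error = function(e) fail_marker(stage, e))
  }

  if (!is.null(config$design)) {
    stage <- "design"
    tryCatch({
      d_cfg <- do.call(design_config, config$design)
      des <- gdls_search(model, d_cfg)
      p7 <- tsv_out(des$trajectory, "design_trajectory.tsv")
      finish_stage(stage, config$design, list(trajectory = p7),
                   list(knockouts = length(des$knockouts),
                        product = des$product, biomass = des$biomass))
    }, error = function(e) fail_marker(stage, e))
  }

  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
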