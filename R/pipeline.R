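# End-to-end orchestration: simulate -> balance -> walks -> cluster ->
# phylogeny -> phase -> loose ends, with a machine-readable manifest.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed (propagated to every stochastic stage).
#' @param depth_sd,dropout simulator noise settings.
#' @param lambda,slack_penalty,min_support balance parameters.
#' @param k_clusters clusters cut from the depth dendrogram.
#' @param posterior_cutoff,max_jaccard,max_gap_bp,min_run phylogeny and
#'   clustering parameters.
#' @return a named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir = tempfile("crisisgraph_run_"), seed = 1L,
                            depth_sd = 0.15, dropout = 0,
                            lambda = 100, slack_penalty = 500,
                            min_support = 1, k_clusters = 6,
                            posterior_cutoff = 0.5, max_jaccard = 0.1,
                            max_gap_bp = 2000, min_run = 2) {
  as.list(environment())
}

#' Run the full analysis pipeline on a simulated compendium
#'
#' Executes every stage in dependency order, writes stage outputs under
#' `cfg$out_dir`, and returns (and writes) a manifest recording
#' parameters, seed, and per-stage status. Rerunning with an identical
#' configuration reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param stages which stages to run (dependencies are not checked:
#'   `balance` needs `simulate`, etc.); defaults to all.
#' @return list with `manifest` and the in-memory stage results.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("simulate", "balance", "walks",
                                    "cluster_depth", "phylo", "rainfall",
                                    "phase", "loose_ends")) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "crisisgraph",
                   version = as.character(utils::packageVersion("crisisgraph")),
                   seed = cfg$seed, parameters = cfg, stages = list())
  results <- list()
  stage <- function(name, fn) {
    if (!(name %in% stages)) {
      manifest$stages[[name]] <<- list(status = "skipped", message = "")
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      message = if (ok) "" else conditionMessage(res))
    if (!ok) abort(sprintf("stage %s failed: %s", name, conditionMessage(res)))
    results[[name]] <<- res
    res
  }

  em <- stage("simulate", function() {
    sc <- crisis_scenario(depth_sd = cfg$depth_sd, dropout = cfg$dropout,
                          seed = cfg$seed)
    em <- emit_clone_data(sc)
    for (cl in names(em$depth))
      write_bedgraph(em$depth[[cl]], file.path(cfg$out_dir, paste0(cl, ".bedgraph")))
    for (cl in names(em$junctions))
      write_bedpe(em$junctions[[cl]], file.path(cfg$out_dir, paste0(cl, ".bedpe")))
    em
  })

  fit <- stage("balance", function() {
    comp <- build_prototype(em$segment_sets,
                            lapply(em$junctions, function(j) j))
    bounds <- derive_edge_bounds(comp, min_support = cfg$min_support)
    fit <- fit_joint(comp, em$depth, bounds,
                     balance_config(lambda = cfg$lambda,
                                    slack_penalty = cfg$slack_penalty,
                                    seed = cfg$seed))
    write_genome_graph(comp$prototype, file.path(cfg$out_dir, "prototype.json"))
    write_cn_bed(fit, file.path(cfg$out_dir, "cn"))
    fit
  })

  stage("walks", function() {
    cl <- names(fit$assignments)[1]
    ws <- enumerate_minimal_walks(fit$graph, fit$assignments[[cl]])
    dec <- decompose_joint(fit$graph, fit$assignments, NULL)
    dec
  })

  stage("cluster_depth", function() {
    coh <- simulate_depth_cohort(seed = cfg$seed, depth_sd = cfg$depth_sd)
    dm <- depth_matrix(coh$matrix, coh$bins)
    cl <- cluster_clones(dm, k = cfg$k_clusters)
    utils::write.table(tibble(clone = names(cl$labels), cluster = cl$labels),
                       file.path(cfg$out_dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(cl$newick, file.path(cfg$out_dir, "depth_dendrogram.nwk"))
    list(clusters = cl, labels_true = coh$labels)
  })

  phylo <- stage("phylo", function() {
    m <- snv_matrix(em$snv$sites, em$snv$counts)
    m <- apply_site_filters(m)
    pm <- presence_posterior(m)
    tree <- neighbor_joining(pm)
    asg <- assign_snvs_to_branches(tree, pm, cfg$max_jaccard)
    ape::write.tree(tree, file.path(cfg$out_dir, "snv_tree.nwk"))
    list(presence = pm, tree = tree, assignment = asg)
  })

  stage("rainfall", function() {
    pres <- phylo$presence
    cl <- colnames(pres$presence)[1]
    snvs <- pres$sites[pres$presence[, cl], c("chrom", "pos")]
    rainfall_clusters(snvs, cfg$max_gap_bp, cfg$min_run)
  })

  stage("phase", function() {
    het <- call_het_sites(em$snp$parental %>%
                            left_join(em$snp$sites, by = "site_id"))
    region <- tibble(chrom = "chrA", start = 0, end = 35e6)
    ph <- phase_by_loss_clone(het, em$snp$counts, "Y11", region)
    acn <- allelic_copy_number(ph, em$snp$counts,
                               norm_sites = het[het$chrom != "chrA" | het$pos >= 35e6, ])
    utils::write.table(acn, file.path(cfg$out_dir, "allelic_cn.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    acn
  })

  stage("loose_ends", function() {
    ev <- tibble(loose_id = fit$loose_ends$uid %||% integer(0),
                 seq = character(length(fit$loose_ends$uid %||% integer(0))))
    if (nrow(ev) == 0) return(tibble())
    screen_loose_ends(ev)
  })

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(manifest = manifest, results = results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
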