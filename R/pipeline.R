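# End-to-end orchestration: synthetic scenario (or user inputs) ->
# imputation -> distances -> ordination -> phylomorphospace ->
# disparity -> disparity-through-time -> complexity -> correlation
# reports, with every stage's artifacts written to an output
# directory plus a machine-readable manifest.

#' Assemble a pipeline configuration
#'
#' @param output_dir Directory for stage artifacts (created if
#'   needed).
#' @param seed Master seed; each stage derives its own stream.
#' @param scenario A [synthetic_scenario()] (defaults to one built
#'   from `seed`).
#' @param n_trees Perturbed tree-sample size for imputation.
#' @param n_sims Stochastic maps per character per tree.
#' @param n_boot Bootstrap replicates for disparity and DTT (0 =
#'   point estimates only).
#' @param bin_Myr DTT slice spacing.
#' @param k Ordination dimensions.
#' @param zero_mode Gower zero handling (see [gower_distance()]).
#' @param dtt_model `"gradual"` or `"punctuated"`.
#' @param n_starts NMDS starts.
#' @param n_perm Mantel permutations.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1L, scenario = NULL,
                            n_trees = 3, n_sims = 100, n_boot = 1000,
                            bin_Myr = 50, k = 2,
                            zero_mode = "ignore_matching_zeros",
                            dtt_model = "gradual", n_starts = 20,
                            n_perm = 999) {
  if (is.null(scenario)) scenario <- synthetic_scenario(seed = seed)
  stopifnot(n_trees >= 1, n_sims >= 1, n_boot >= 0, bin_Myr > 0, k >= 1)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 scenario = scenario, n_trees = n_trees, n_sims = n_sims,
                 n_boot = n_boot, bin_Myr = bin_Myr, k = k,
                 zero_mode = zero_mode, dtt_model = dtt_model,
                 n_starts = n_starts, n_perm = n_perm),
            class = "pipeline_config")
}

# Derived per-stage seeds, all below 2^31.
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 1009) %% 2147483647
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full disparity pipeline on a synthetic scenario
#'
#' Generates the scenario data, imputes missing states over the tree
#' sample, builds Gower and patristic distances, ordinates tips and
#' reconstructed nodes jointly (NMDS, with a PCoA concordance check),
#' computes clade disparity and the disparity-through-time curve,
#' scores complexity and its ploidy correlation, and writes one file
#' per artifact plus `manifest.json`. With a fixed config and seed the
#' outputs are byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  res <- list(config = config)

  say("stage 1/8: synthetic data")
  bundle <- simulate_scenario(config$scenario, n_trees = config$n_trees)
  res$bundle <- bundle
  write_character_matrix(bundle$matrix, file.path(out, "matrix.csv"))
  write_character_matrix(bundle$truth$matrix,
                         file.path(out, "matrix_truth.csv"))
  ape::write.tree(bundle$tree, file.path(out, "tree.nwk"))
  ape::write.tree(structure(unclass(bundle$trees), class = "multiPhylo"),
                  file.path(out, "tree_sample.nwk"))
  .write_csv(data.frame(edge = seq_along(bundle$ploidy$branch_events),
                        events = bundle$ploidy$branch_events),
             file.path(out, "ploidy_branches.csv"))

  say("stage 2/8: imputation (", config$n_trees, " trees x ",
      config$n_sims, " maps)")
  imp <- impute_matrix(bundle$matrix, bundle$trees,
                       n_sims = config$n_sims,
                       seed = .stage_seed(config$seed, 2))
  res$imputation <- imp
  write_character_matrix(imp$focal, file.path(out, "focal.csv"))
  write_character_matrix(imp$combined, file.path(out, "focal_nodes.csv"))
  .write_csv(imp$details, file.path(out, "imputation_details.csv"))

  say("stage 3/8: distances")
  gd <- gower_distance(imp$combined, zero_mode = config$zero_mode)
  res$gower <- gd
  write_dissimilarity(gd, file.path(out, "gower.csv"))
  pat <- patristic_distances(bundle$tree)
  res$patristic <- pat

  say("stage 4/8: ordination")
  ord <- nmds(gd, k = config$k, n_starts = config$n_starts,
              seed = .stage_seed(config$seed, 4))
  res$nmds <- ord
  res$pcoa <- pcoa(gd, k = config$k)
  coords <- data.frame(unit = ord$labels,
                       is_node = ord$labels %in% imp$node_labels,
                       ord$coordinates)
  names(coords)[-(1:2)] <- paste0("axis", seq_len(ncol(ord$coordinates)))
  .write_csv(coords, file.path(out, "nmds_coordinates.csv"))
  .write_csv(ord$shepard, file.path(out, "shepard.csv"))

  say("stage 5/8: phylomorphospace")
  pm <- phylomorphospace(imp$combined, bundle$tree,
                         distance_fun = function(m)
                           gower_distance(m, zero_mode = config$zero_mode),
                         ordination_fun = function(d) ord)
  res$phylomorphospace <- pm
  .write_csv(pm$edges, file.path(out, "phylomorphospace_edges.csv"))

  say("stage 6/8: disparity and DTT")
  groups <- basal_clade_groups(bundle$tree)
  res$groups <- groups
  md <- mean_disparity(gd, groups, n_boot = config$n_boot,
                       seed = .stage_seed(config$seed, 6))
  pd <- partial_disparity(ord, groups, n_boot = config$n_boot,
                          seed = .stage_seed(config$seed, 6) + 1)
  res$mean_disparity <- md
  res$partial_disparity <- pd
  .write_csv(md, file.path(out, "mean_disparity.csv"))
  .write_csv(pd, file.path(out, "partial_disparity.csv"))
  curve <- dtt(ord, bundle$tree, model = config$dtt_model,
               bin_Myr = config$bin_Myr, n_boot = config$n_boot,
               seed = .stage_seed(config$seed, 7))
  res$dtt <- curve
  .write_csv(curve, file.path(out, "dtt.csv"))

  say("stage 7/8: complexity")
  pres <- recode_presence(imp$focal, default_presence_recode(imp$focal))
  scores <- complexity_scores(pres)
  scores$prop_applicable <- vapply(scores$taxon, function(tx)
    applicable_proportion(imp$focal, tx), numeric(1))
  res$complexity <- scores
  .write_csv(scores, file.path(out, "complexity.csv"))
  pcc <- ploidy_complexity_correlation(
    stats::setNames(scores$score, scores$taxon), bundle$ploidy,
    bundle$tree, method = "pic_pearson")
  res$ploidy_correlation <- pcc
  report_json(pcc, file.path(out, "ploidy_correlation.json"))

  say("stage 8/8: correlation reports")
  seed8 <- .stage_seed(config$seed, 8)
  tips <- bundle$tree$tip.label
  gd_tips <- dissimilarity(gd$values[tips, tips],
                           flagged = gd$flagged[tips, tips])
  res$mantel_patristic <- mantel_test(gd_tips, pat[tips, tips],
                                      n_perm = config$n_perm, seed = seed8)
  res$concordance <- ordination_concordance(res$nmds, res$pcoa,
                                            n_perm = config$n_perm,
                                            seed = seed8 + 1)
  report_json(res$mantel_patristic,
              file.path(out, "mantel_patristic.json"))
  report_json(res$concordance, file.path(out, "nmds_pcoa_concordance.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("morphodisp")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      vapply(1:8, function(s) .stage_seed(config$seed, s), numeric(1)),
      paste0("stage", 1:8)),
    parameters = config[setdiff(names(config), c("output_dir",
                                                 "scenario"))],
    scenario = unclass(config$scenario),
    nmds_stress = res$nmds$stress,
    files = sort(setdiff(list.files(out), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out)
  invisible(res)
}

#' Group tips by the root's child clades
#'
#' A simple clade assignment for synthetic scenarios: each tip is
#' labelled by which child clade of the root it belongs to
#' ("clade_A", "clade_B", ...).
#'
#' @param tree Rooted `phylo`.
#' @return Named character vector tip -> group.
#' @export
basal_clade_groups <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  groups <- stats::setNames(rep(NA_character_, ntip), tree$tip.label)
  for (ci in seq_along(kids)) {
    tips <- if (kids[ci] <= ntip) kids[ci] else {
      desc <- phangorn_free_descendants(tree, kids[ci])
      desc[desc <= ntip]
    }
    groups[tree$tip.label[tips]] <- paste0("clade_", LETTERS[ci])
  }
  groups
}

#' Default presence recode table
#'
#' Maps every multistate character's state 0 to absent and all
#' positive states to present; binary characters pass through. A
#' domain-curated recode table should replace this for real matrices,
#' where state 0 is not always "absent".
#'
#' @param m A [character_matrix()].
#' @return Named list suitable for [recode_presence()].
#' @export
default_presence_recode <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  out <- list()
  for (ch in characters(m)) {
    col <- m$cells[, ch]
    states <- sort(unique(col[!is.na(col) & col != INAPPLICABLE]))
    if (length(states) && max(states) > 1L) {
      map <- stats::setNames(as.numeric(states > 0L), states)
      out[[ch]] <- map
    }
  }
  out
}
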