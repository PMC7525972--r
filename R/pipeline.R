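pipeline_defaults <- function() list(
  seed = 1L,
  outdir = "glvnet-output",
  input = NULL,          # list(shared = path, metadata = path)
  synthetic = NULL,      # study_design fields
  ensemble = list(mode = "subsample", n_subsample = 2000, ceiling = 2e5),
  consensus = list(cutoff = 0.7, include_self = FALSE),
  regression = list(backend = "pls", n_components = 2, lambda = 1e-2,
                    pseudocount = NULL),
  membership = list(high_cutoff = 0.01, rare_cutoff = 0.001,
                    scope = "per_group"),
  focal = character(0))

merge_known <- function(defaults, given, path, errors) {
  for (key in names(given)) {
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs,
                       sprintf("unknown config key '%s%s'", path, key))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]]) &&
        !is.null(given[[key]])) {
      if (!is.list(given[[key]])) {
        errors$msgs <- c(errors$msgs,
                         sprintf("'%s%s' must be a mapping", path, key))
        next
      }
      defaults[[key]] <- merge_known(defaults[[key]], given[[key]],
                                     paste0(path, key, "."), errors)
    } else defaults[[key]] <- given[[key]]
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults (consensus cutoff
#' 0.7, regression backend pls, subsampled ensemble of 2000, ...), and
#' collects every problem -- including any unknown key, so typos never pass
#' silently. Exactly one of `input` (shared + metadata paths) or `synthetic`
#' (study-design fields for [study_design()]) must be present.
#'
#' @param config path to a YAML file, or a named list.
#' @return normalized config list of class `pipeline_config`, or an error
#'   listing every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML mapping or a list")
  errors <- new.env()
  errors$msgs <- character(0)
  defaults <- pipeline_defaults()
  # input/synthetic have no defaults to merge into; validate separately
  top <- config[setdiff(names(config), c("input", "synthetic"))]
  cfg <- merge_known(defaults[setdiff(names(defaults),
                                      c("input", "synthetic"))],
                     top, "", errors)
  cfg$input <- config$input
  cfg$synthetic <- config$synthetic
  if (is.null(cfg$input) == is.null(cfg$synthetic))
    errors$msgs <- c(errors$msgs,
                     "exactly one of 'input' or 'synthetic' must be given")
  if (!is.null(cfg$input) &&
      !all(c("shared", "metadata") %in% names(cfg$input)))
    errors$msgs <- c(errors$msgs, "'input' needs keys shared and metadata")
  if (!is.null(cfg$synthetic)) {
    allowed <- setdiff(names(formals(study_design)), "seed")
    bad <- setdiff(names(cfg$synthetic), allowed)
    if (length(bad))
      errors$msgs <- c(errors$msgs,
                       sprintf("unknown config key 'synthetic.%s'", bad))
  }
  cc <- cfg$consensus$cutoff
  if (!is.numeric(cc) || length(cc) != 1 || cc <= 0 || cc >= 1)
    errors$msgs <- c(errors$msgs, "'consensus.cutoff' must lie in (0, 1)")
  if (!cfg$regression$backend %in% c("pls", "ridge", "ols"))
    errors$msgs <- c(errors$msgs,
                     "'regression.backend' must be pls, ridge or ols")
  if (!cfg$ensemble$mode %in% c("full", "subsample"))
    errors$msgs <- c(errors$msgs, "'ensemble.mode' must be full or subsample")
  if (!cfg$membership$scope %in% c("per_group", "all_samples"))
    errors$msgs <- c(errors$msgs,
                     "'membership.scope' must be per_group or all_samples")
  if (length(errors$msgs))
    abort("invalid config:\n  - %s", paste(errors$msgs, collapse = "\n  - "))
  cfg$seed <- assert_count(cfg$seed, "seed", min = 0L)
  cfg$focal <- as.character(cfg$focal)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) the abundance table, classify membership, compute
#' alpha diversity, infer the per-group gLV ensemble and consensus network,
#' compute topology reports, compare stability between the first two groups,
#' and write every artifact under `outdir`. A JSON manifest records the
#' config snapshot, the seed and an md5 checksum for every file, so reruns
#' with the same config are byte-comparable.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @param outdir overrides the config's output directory.
#' @return the manifest, invisibly (list with `config`, `files`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, code)
    tryCatch(code, error = function(e)
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  files <- character(0)
  emit <- function(rel, writer) {
    path <- file.path(outdir, rel)
    writer(path)
    files <<- c(files, path)
    path
  }

  table <- stage("load", {
    if (!is.null(config$input)) {
      read_abundance_table(config$input$shared, config$input$metadata)
    } else {
      design <- do.call(study_design,
                        c(config$synthetic, list(seed = seed)))
      study <- generate_study(design)
      emit("synthetic_truth.json", function(p)
        jsonlite::write_json(lapply(study$params, function(pp)
          list(growth = unname(pp$growth),
               interactions = unname(pp$interactions), taxa = pp$taxa)),
          p, auto_unbox = TRUE, digits = NA))
      emit("shared.tsv", function(p)
        write_abundance_table(study$table, p, file.path(outdir, "metadata.tsv")))
      emit("metadata.tsv", function(p) invisible(p))  # written just above
      study$table
    }
  })
  groups <- unique(table$metadata$group)

  stage("classify", emit("membership.csv", function(p)
    utils::write.csv(classify_membership(
      table, config$membership$high_cutoff, config$membership$rare_cutoff,
      config$membership$scope), p, row.names = FALSE)))
  stage("diversity", emit("diversity.csv", function(p)
    utils::write.csv(alpha_diversity_table(table), p, row.names = FALSE)))

  fit_cfg <- glv_fit_config(config$regression$backend,
                            n_components = config$regression$n_components,
                            lambda = config$regression$lambda,
                            pseudocount = config$regression$pseudocount)
  profiles <- list()
  for (g in groups) {
    meta_g <- table$metadata[table$metadata$group == g, ]
    R <- length(unique(meta_g$mouse))
    K <- length(unique(meta_g$day))
    assemblies <- stage(paste0("assemblies:", g),
      enumerate_assemblies(R, K, mode = config$ensemble$mode,
                           n_subsample = config$ensemble$n_subsample,
                           seed = seed, ceiling = config$ensemble$ceiling))
    ens <- stage(paste0("infer:", g),
                 infer_ensemble(table, g, assemblies, fit_cfg))
    net <- stage(paste0("consensus:", g),
                 consensus_network(ens, config$consensus$cutoff,
                                   config$consensus$include_self))
    emit(sprintf("network_%s.csv", g), function(p) write_network_edges(net, p))
    emit(sprintf("network_%s.graphml", g),
         function(p) write_network_graphml(net, p))
    emit(sprintf("network_%s.gexf", g), function(p) write_network_gexf(net, p))
    report <- stage(paste0("topology:", g), rank_aggregate(net))
    emit(sprintf("centrality_%s.csv", g), function(p)
      utils::write.csv(report, p, row.names = FALSE))
    for (focal in intersect(config$focal, net$taxa))
      emit(sprintf("focal_%s_%s.csv", g, focal), function(p)
        utils::write.csv(as.data.frame(focal_report(net, focal)), p,
                         row.names = FALSE))
    profiles[[g]] <- stage(paste0("stability:", g),
                           suppressWarnings(stability_profile(ens, net, g)))
    emit(sprintf("stability_%s.csv", g), function(p)
      utils::write.csv(cbind(group = g, profiles[[g]]$members), p,
                       row.names = FALSE))
  }
  if (length(groups) >= 2L) {
    cmp <- stage("compare_stability",
                 compare_stability(profiles[[groups[1]]],
                                   profiles[[groups[2]]], seed = seed))
    emit("stability_comparison.json", function(p)
      jsonlite::write_json(c(cmp["group_a"], cmp["group_b"],
                             lapply(cmp[c("shapiro_p_a", "shapiro_p_b",
                                          "wilcoxon_p_positive",
                                          "wilcoxon_p_negative")], unname),
                             cmp["direction"], list(seed = seed)),
                           p, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  manifest <- list(
    config = unclass(config),
    seed = seed,
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(manifest)
}
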