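#' Run the full simulate-adjust-predict pipeline
#'
#' Orchestrates every stage on one configuration: simulate (or read)
#' genotypes, traits, field layout and reflectance; average scans and
#' compute spectral indices; adjust plots to genotype-level BLUEs; marker
#' QC, imputation and GRM; replicated cross-validation of the univariate
#' and index-bearing models; and the improvement summary. Each stage
#' writes its artifact to \code{out_dir} together with a machine-readable
#' run manifest (seed, package version, config hash). Any stage failure
#' aborts with the stage name; artifacts written so far are retained.
#'
#' @param config either a \code{\link{sim_config}} or the path to a YAML
#'   file of \code{sim_config} arguments.
#' @param out_dir output directory (created if needed).
#' @param models model tags to cross-validate.
#' @param replicates CV replicates per model.
#' @param k CV folds.
#' @param primary trait treated as primary (default first configured
#'   trait).
#' @param sri_axes index columns used as secondary traits.
#' @param quiet suppress progress messages.
#' @return invisible list with the stage artifacts (values carry the
#'   config hash as attribute \code{config_hash}).
#' @export
run_pipeline <- function(config, out_dir = tempfile("phenogs_run_"),
                         models = c("unigs", "srir", "gs_sri", "multigs"),
                         replicates = 10, k = 5, primary = NULL,
                         sri_axes = c("NDVI", "NWI", "PRI"), quiet = FALSE) {
  if (is.character(config)) config <- do.call(sim_config, yaml::read_yaml(config))
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ## manifest: config + seed + version, hashed for provenance
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.matrix(x)) as.vector(x) else x), cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  manifest <- list(config_hash = hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("phenogs")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  stamp <- function(x) { attr(x, "config_hash") <- hash; x }

  primary <- primary %||% config$trait_names[1]
  say("simulate: genotypes")
  geno <- stage("simulate_genotypes", simulate_nam_genotypes(config))
  write_genotypes(unclass(geno)[, , drop = FALSE],
                  file.path(out_dir, "genotypes.csv"))
  say("simulate: traits + field layout")
  tr <- stage("simulate_traits", simulate_traits(geno, config))
  plots <- stage("simulate_layout", simulate_field_layout(tr$values, config))
  write_phenotypes(plots, file.path(out_dir, "plots.csv"))
  say("simulate: reflectance")
  sri_latent <- plots
  for (ax in sri_axes)
    if (!ax %in% names(sri_latent)) stop("sri axis ", ax, " not among traits")
  refl <- stage("simulate_reflectance", {
    sl <- sri_latent; sl$stage <- "heading"
    simulate_reflectance(sl, config)
  })
  write_reflectance(refl, file.path(out_dir, "reflectance.csv"))

  say("spectral: average + indices")
  panel <- stage("spectral_average", average_plot_reflectance(refl))
  sri_plot <- stage("spectral_indices", compute_indices(panel))
  utils::write.csv(sri_plot, file.path(out_dir, "sri.csv"), row.names = FALSE)

  say("adjust: BLUEs per environment")
  blues <- stage("trial_adjustment", {
    out <- lapply(config$trait_names, function(t2) fit_acbd_blue(plots, t2))
    do.call(rbind, out)
  })
  utils::write.csv(blues, file.path(out_dir, "blues.csv"), row.names = FALSE)

  say("genomics: QC + GRM")
  m <- stage("qc", qc_filter(unclass(geno)[!attr(geno, "is_check"), , drop = FALSE]))
  utils::write.table(attr(m, "qc_report"), file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  G <- stage("grm", compute_grm(impute_missing(m)))

  say("evaluate: cross-validation (", replicates, " replicates)")
  env1 <- unique(blues$environment)[1]
  b1 <- blues[blues$environment == env1 & blues$trait == primary &
                !blues$is_check, ]
  lines <- intersect(b1$genotype_id, rownames(G))
  y <- stats::setNames(b1$value[match(lines, b1$genotype_id)], lines)
  ## genotype-level secondary traits: BLUE-adjust the latent index columns
  sri_blues <- lapply(sri_axes, function(ax) {
    bb <- fit_acbd_blue(plots, ax)
    bb <- bb[bb$environment == env1 & !bb$is_check, ]
    stats::setNames(bb$value[match(lines, bb$genotype_id)], lines)
  })
  sri <- do.call(cbind, sri_blues)
  colnames(sri) <- sri_axes
  cvs <- list()
  for (mod in models) {
    cvs[[mod]] <- stage(paste0("cv_", mod),
                        kfold_cv(y, G[lines, lines], sri = sri, model = mod,
                                 k = k, replicates = replicates, sets = 1,
                                 seed = config$seed))
  }
  acc <- vapply(cvs, `[[`, numeric(1), "mean")
  cv_tab <- data.frame(model = names(acc), accuracy = unname(acc),
                       se = vapply(cvs, `[[`, numeric(1), "se"))
  utils::write.csv(cv_tab, file.path(out_dir, "cv_accuracy.csv"),
                   row.names = FALSE)
  improvement <- NULL
  if (all(c("unigs", "multigs") %in% names(acc))) {
    improvement <- summarize_improvement(acc[["unigs"]], acc[["multigs"]],
                                         environments = env1)
    utils::write.csv(as.data.frame(improvement),
                     file.path(out_dir, "improvement.csv"), row.names = FALSE)
  }
  say("done; artifacts in ", out_dir)
  invisible(stamp(list(config = config, genotypes = geno, plots = plots,
                       reflectance = refl, sri = stamp(sri_plot),
                       blues = stamp(blues), grm = G, cv = cvs,
                       cv_table = stamp(cv_tab), improvement = improvement,
                       manifest = manifest, out_dir = out_dir)))
}
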