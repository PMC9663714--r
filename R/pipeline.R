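# Pipeline orchestration: simulate -> cohort -> rank -> validate.
#
# Each stage reads its predecessor's on-disk artifacts, so stages are
# independently rerunnable; a run manifest records the config hash, seed,
# package version and per-stage row counts. The global seed is expanded
# into fixed per-stage substreams, making reruns byte-reproducible.

#' Assemble a pipeline configuration
#'
#' @param sim a [sim_config()] for the generator stage.
#' @param bcaus a [bcaus_config()] shared by all case-comparator studies.
#' @param seed global seed, expanded deterministically per stage.
#' @param train_fraction training fraction of the snapshot-level split.
#' @param split_by_patient split at patient level instead.
#' @param B bootstrap replicates per study.
#' @param min_arm regimens need strictly more than this many training
#'   snapshots in a cohort to enter its network.
#' @param min_cohort minimum training snapshots for a cohort to be ranked.
#' @param baseline baseline regimen for the NMA.
#' @param nma list of MCMC settings passed to [fit_nma()]
#'   (`n_chains`, `n_warmup`, `n_iter`).
#' @param sucra_draws ranking draws for [sucra_ranks()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), bcaus = bcaus_config(),
                            seed = 1L, train_fraction = 0.8,
                            split_by_patient = FALSE, B = 200L,
                            min_arm = 35L, min_cohort = 100L,
                            baseline = "metformin",
                            nma = list(n_chains = 4L, n_warmup = 2000L,
                                       n_iter = 2500L),
                            sucra_draws = 4000L) {
  structure(list(sim = sim, bcaus = bcaus, seed = as.integer(seed),
                 train_fraction = train_fraction,
                 split_by_patient = split_by_patient, B = as.integer(B),
                 min_arm = as.integer(min_arm),
                 min_cohort = as.integer(min_cohort), baseline = baseline,
                 nma = nma, sucra_draws = as.integer(sucra_draws)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.update_manifest <- function(outdir, config, stage, counts) {
  path <- file.path(outdir, "manifest.json")
  man <- if (file.exists(path)) jsonlite::read_json(path) else
    list(config_hash = .config_hash(config), seed = config$seed,
         package_version = as.character(utils::packageVersion("glycorank")),
         stages = list())
  man$stages[[stage]] <- counts
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

.need_artifact <- function(path, stage_needed) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run stage '",
         stage_needed, "' first", call. = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` writes the four-table synthetic claims schema;
#' `cohort` builds filtered snapshots, confounders, the train/test split
#' and a cohort summary; `rank` runs all pairwise studies, the NMA and
#' SUCRA ranking per eligible cohort on training snapshots; `validate`
#' evaluates concordance on train and held-out test snapshots, the tiered
#' sensitivity analysis and rank trajectories. `all` runs everything in
#' order. Rerunning a stage with the same config and seed reproduces its
#' artifacts.
#'
#' @param stage one of "simulate", "cohort", "rank", "validate", "all".
#' @param config a [pipeline_config()].
#' @param outdir artifact directory (created if needed).
#' @return invisibly, a list of the stage's principal outputs.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "cohort", "rank",
                                   "validate"),
                         config = pipeline_config(), outdir) {
  stage <- match.arg(stage)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in c("simulate", "cohort", "rank", "validate"))
      out <- run_pipeline(s, config, outdir)
    return(invisible(out))
  }
  switch(stage,
         simulate = .stage_simulate(config, outdir),
         cohort = .stage_cohort(config, outdir),
         rank = .stage_rank(config, outdir),
         validate = .stage_validate(config, outdir))
}

.stage_simulate <- function(config, outdir) {
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "simulate")
  pop <- simulate_population(sim)
  write_tables(pop, file.path(outdir, "data"))
  .update_manifest(outdir, config, "simulate",
                   list(patients = nrow(pop$demographics),
                        labs = nrow(pop$labs),
                        prescriptions = nrow(pop$prescriptions)))
  invisible(list(population = pop))
}

.stage_cohort <- function(config, outdir) {
  .need_artifact(file.path(outdir, "data", "labs.csv"), "simulate")
  pop <- read_tables(file.path(outdir, "data"))
  pop <- apply_exclusions(pop)
  snapshots <- build_snapshots(pop)
  if (nrow(snapshots) == 0L)
    stop("no snapshots survive filtering", call. = FALSE)
  X <- assemble_confounders(pop, snapshots)
  split <- split_train_test(snapshots,
                            fraction = config$train_fraction,
                            seed = derive_seed(config$seed, "cohort"),
                            by_patient = config$split_by_patient, X = NULL)
  snapshots$dataset <- "test"
  snapshots$dataset[split$train] <- "train"
  utils::write.csv(snapshots, file.path(outdir, "snapshots.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(snapshot_id = rownames(X), as.data.frame(X)),
                   file.path(outdir, "confounders.csv"), row.names = FALSE)
  utils::write.csv(cohort_summary(snapshots),
                   file.path(outdir, "cohort_summary.csv"),
                   row.names = FALSE)
  .update_manifest(outdir, config, "cohort", c(
    list(snapshots = nrow(snapshots), train = length(split$train),
         test = length(split$test)),
    as.list(attr(snapshots, "filter_log")),
    list(excluded_patients =
           length(unique(attr(pop, "exclusion_log")$patient_id)))))
  invisible(list(snapshots = snapshots, X = X))
}

.read_cohort_artifacts <- function(outdir) {
  sn <- utils::read.csv(.need_artifact(file.path(outdir, "snapshots.csv"),
                                       "cohort"), stringsAsFactors = FALSE)
  Xdf <- utils::read.csv(file.path(outdir, "confounders.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  X <- as.matrix(Xdf[, -1, drop = FALSE])
  rownames(X) <- Xdf[[1]]
  list(snapshots = sn, X = X[sn$snapshot_id, , drop = FALSE])
}

# Per-cohort imputation using training-set means, returning complete
# matrices aligned with the cohort's train/test rows.
.impute_cohort <- function(X, train_rows) {
  tr <- impute_to_means(X[train_rows, , drop = FALSE])
  full <- impute_to_means(X, means = tr$means)
  full$X
}

.stage_rank <- function(config, outdir) {
  art <- .read_cohort_artifacts(outdir)
  sn <- art$snapshots
  seed <- derive_seed(config$seed, "rank")
  rankings <- list(); effects_all <- list(); networks <- list()
  skipped <- list()
  for (co in sort(unique(sn$cohort))) {
    rows <- which(sn$cohort == co & sn$dataset == "train")
    if (length(rows) < config$min_cohort) {
      skipped[[co]] <- "below min_cohort training snapshots"
      next
    }
    sco <- sn[rows, , drop = FALSE]
    Xco <- .impute_cohort(art$X[rows, , drop = FALSE],
                          seq_along(rows))
    counts <- table(sco$regimen)
    eligible <- names(counts)[counts > config$min_arm]
    if (length(eligible) < 2L) {
      skipped[[co]] <- "fewer than 2 regimens above the node-size cutoff"
      next
    }
    eff <- run_all_pairs(sco, Xco, eligible, config$bcaus, B = config$B,
                         seed = seed + match(co, LETTERS))
    if (nrow(eff) == 0L) {
      skipped[[co]] <- "no pairwise study completed"
      next
    }
    net <- build_network(eff, counts, baseline = config$baseline,
                         min_arm = config$min_arm)
    if (nrow(net$nodes) < 2L || nrow(net$edges) == 0L) {
      skipped[[co]] <- "network empty after trimming"
      next
    }
    post <- fit_nma(net, n_chains = config$nma$n_chains,
                    n_warmup = config$nma$n_warmup,
                    n_iter = config$nma$n_iter,
                    seed = seed + match(co, LETTERS))
    rk <- sucra_ranks(post, net, n_draws = config$sucra_draws,
                      seed = seed + match(co, LETTERS),
                      force = TRUE)
    rk <- cbind(cohort = co, rk, converged = post$converged)
    rankings[[co]] <- rk
    effects_all[[co]] <- eff
    networks[[co]] <- list(
      nodes = net$nodes, edges = net$edges, baseline = net$baseline,
      baseline_substituted = net$baseline_substituted)
  }
  if (!length(rankings))
    stop("no cohort could be ranked: ",
         paste(names(skipped), unlist(skipped), sep = ": ",
               collapse = "; "), call. = FALSE)
  rk_tab <- do.call(rbind, rankings)
  ef_tab <- do.call(rbind, effects_all)
  rownames(rk_tab) <- rownames(ef_tab) <- NULL
  utils::write.csv(rk_tab, file.path(outdir, "rankings.csv"),
                   row.names = FALSE)
  utils::write.csv(ef_tab, file.path(outdir, "pairwise_effects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(networks, file.path(outdir, "networks.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  .update_manifest(outdir, config, "rank",
                   list(cohorts_ranked = length(rankings),
                        cohorts_skipped = length(skipped),
                        skip_reasons = skipped,
                        studies = nrow(ef_tab),
                        ranked_regimens = nrow(rk_tab)))
  invisible(list(rankings = rk_tab, effects = ef_tab,
                 networks = networks, skipped = skipped))
}

.stage_validate <- function(config, outdir) {
  art <- .read_cohort_artifacts(outdir)
  rk_tab <- utils::read.csv(.need_artifact(
    file.path(outdir, "rankings.csv"), "rank"), stringsAsFactors = FALSE)
  sn <- art$snapshots
  seed <- derive_seed(config$seed, "validate")
  conc <- list(); tiers <- list(); traj <- list()
  for (co in unique(rk_tab$cohort)) {
    rk <- rk_tab[rk_tab$cohort == co, , drop = FALSE]
    rows_all <- which(sn$cohort == co)
    tr_local <- which(sn$dataset[rows_all] == "train")
    Xco <- .impute_cohort(art$X[rows_all, , drop = FALSE], tr_local)
    for (ds in c("train", "test")) {
      sel <- sn$dataset[rows_all] == ds
      conc[[paste(co, ds)]] <- evaluate_concordance(
        sn[rows_all[sel], , drop = FALSE], Xco[sel, , drop = FALSE], rk,
        dataset = ds, config = config$bcaus, B = config$B,
        seed = seed + match(co, LETTERS))
    }
    tr <- sn$dataset[rows_all] == "train"
    ti <- sensitivity_tiers(sn[rows_all[tr], , drop = FALSE],
                            Xco[tr, , drop = FALSE], rk,
                            config = config$bcaus, B = config$B,
                            seed = seed + match(co, LETTERS))
    tiers[[co]] <- cbind(cohort = co, ti)
    tj <- rank_trajectories(sn[rows_all, , drop = FALSE], rk)
    traj[[co]] <- cbind(cohort = co,
                        as.data.frame(tj, stringsAsFactors = FALSE))
  }
  conc_tab <- do.call(rbind, conc)
  tier_tab <- do.call(rbind, tiers)
  traj_tab <- do.call(rbind, traj)
  rownames(conc_tab) <- rownames(tier_tab) <- rownames(traj_tab) <- NULL
  utils::write.csv(conc_tab, file.path(outdir, "concordance.csv"),
                   row.names = FALSE)
  utils::write.csv(tier_tab, file.path(outdir, "sensitivity_tiers.csv"),
                   row.names = FALSE)
  utils::write.csv(traj_tab, file.path(outdir, "rank_trajectories.csv"),
                   row.names = FALSE)
  .update_manifest(outdir, config, "validate",
                   list(concordance_rows = nrow(conc_tab),
                        significant = sum(conc_tab$significant),
                        tier_rows = nrow(tier_tab)))
  invisible(list(concordance = conc_tab, tiers = tier_tab,
                 trajectories = traj_tab))
}
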