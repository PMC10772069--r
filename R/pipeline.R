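# End-to-end orchestration: simulate -> completeness -> periods -> MDS ->
# trajectories -> MRCA curves -> gene-drop IBD bins -> manifest. All tables
# are CSV with headers; numeric columns are written at 10 significant
# digits; a run is a pure function of (config, seed).

.write_csv10 <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic sub-seeds per stage from one master seed
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 1L, mds = 2L, trends = 3L, mrca = 4L, genedrop = 5L)
  as.integer((as.numeric(seed) * 7919 + offs[[stage]] * 104729) %% (2^31 - 1))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a pedigree, then writes per-stage CSV outputs under
#' `out_dir`: the pedigree, per-group completeness, period assignment,
#' per-period MDS coordinates, group kinship/inbreeding trajectories, MRCA
#' curves and gene-drop IBD sharing bins, plus a YAML run manifest with md5
#' checksums of every output.
#'
#' @param config a [scenario_config()], or the path of a YAML scenario file
#' @param out_dir output directory (created if needed)
#' @param seed master seed; fanned out deterministically to the simulation,
#'   bootstrap and gene-drop stages (default: the config seed)
#' @param stages subset of
#'   `c("simulate", "completeness", "periods", "mds", "trends", "mrca", "genedrop")`
#' @param max_meioses,boot_n,boot_reps MRCA-curve parameters
#' @param max_pairs cap on pairs per period/group in the kinship-mean and
#'   IBD stages (keeps large runs tractable; means stay unbiased)
#' @param mds_min_members periods with fewer eligible members are skipped
#' @param verbose print stage progress
#' @return the run manifest, invisibly (also written to `manifest.yaml`)
#' @export
run_all <- function(config, out_dir, seed = NULL,
                    stages = c("simulate", "completeness", "periods", "mds",
                               "trends", "mrca", "genedrop"),
                    max_meioses = 30L, boot_n = 47L, boot_reps = 1000L,
                    max_pairs = 20000L, mds_min_members = 3L,
                    verbose = TRUE) {
  t0 <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- read_scenario(config)
  }
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_csv10(df, p)
    outputs <<- c(outputs, p)
    p
  }

  config$seed <- .stage_seed(seed, "simulate")
  say("[simulate] seed %d", config$seed)
  ped <- simulate_genealogy(config)
  say("[simulate] %d individuals, %d probands", nrow(ped$ind),
      length(ped$proband_ids))
  ped_path <- file.path(out_dir, "pedigree.csv")
  write_pedigree(ped, ped_path)
  outputs <- c(outputs, ped_path)

  if ("completeness" %in% stages) {
    say("[completeness]")
    emit(completeness_by_group(ped, max_gen = 12L), "completeness.csv")
  }

  assignment <- NULL
  if (any(c("periods", "mds", "trends") %in% stages)) {
    say("[periods]")
    assignment <- assign_periods(ped)
    per <- assignment
    per$imputed <- per$id %in% attr(assignment, "imputed")
    emit(per, "periods.csv")
    emit(data.frame(statistic = "parent_child_same_bin_overlap",
                    value = attr(assignment, "overlap")),
         "period_overlap.csv")
  }

  if ("mds" %in% stages) {
    anc_ids <- ped$ind$id[.ancestor_rows(ped, .row_of(ped, ped$proband_ids))]
    set.seed(.stage_seed(seed, "mds"))
    for (p in sort(unique(assignment$period))) {
      mem <- intersect(assignment$id[assignment$period == p], anc_ids)
      if (length(mem) < mds_min_members) next
      res <- tryCatch(period_mds(ped, assignment, p, ids = anc_ids),
                      error = function(e) NULL)
      if (is.null(res)) next
      say("[mds] %s: %d ancestors (%d removed)", p, nrow(res),
          length(attr(res, "removed")))
      emit(res, paste0("mds_", gsub("-", "_", p), ".csv"))
    }
  }

  if ("trends" %in% stages) {
    say("[trends]")
    set.seed(.stage_seed(seed, "trends"))
    emit(group_trajectories(ped, assignment, max_pairs = max_pairs),
         "trajectories.csv")
  }

  if ("mrca" %in% stages) {
    groups <- sort(unique(stats::na.omit(ped$group_of)))
    curves <- list()
    for (g in groups) {
      say("[mrca] group %s", g)
      curves[[g]] <- as.data.frame(
        group_curves(ped, g, max_meioses = max_meioses, boot_n = boot_n,
                     boot_reps = boot_reps, seed = .stage_seed(seed, "mrca")))
    }
    emit(do.call(rbind, curves), "mrca_curves.csv")
  }

  if ("genedrop" %in% stages) {
    say("[genedrop]")
    drop <- gene_drop(ped, genome_map(), seed = .stage_seed(seed, "genedrop"))
    sh <- group_ibd_sharing(ped, drop, max_pairs = max_pairs)
    emit(sh$bins, "ibd_bins.csv")
    emit(sh$segments, "ibd_segments.csv")
  }

  manifest <- list(
    seed = as.integer(seed),
    stage_seeds = lapply(stats::setNames(nm = c("simulate", "mds", "trends",
                                                "mrca", "genedrop")),
                         function(s) .stage_seed(seed, s)),
    n_individuals = nrow(ped$ind),
    n_probands = length(ped$proband_ids),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("done: %d output files", length(outputs))
  invisible(manifest)
}
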