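# Stage orchestration: runs the analysis stages in dependency order on
# a directory of inputs, writing TSV artifacts plus a JSON manifest.

#' Pipeline run configuration
#'
#' Collects every stage parameter with its conventional default: block
#' filter of at least 10 usable pairs, Ks fitting window (0, 3],
#' calibration interval 115-130 Ma, mu = 7.06e-9 per site per year,
#' alpha = 0.05, GO categories tested above 20 members, 1 kb proximity
#' bin.
#'
#' @param seed Integer seed for all stochastic stages.
#' @param ... Overrides for any element.
#' @return A named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 20221214L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    min_pairs = 10L,
    ks_max = 5,
    ks_window = c(0, 3),
    k = 3L,
    cal = c(115, 130),
    mu = 7.06e-9,
    alpha = 0.05,
    min_orthologs = 21L,
    bin_edge_bp = 1000L,
    ltr_bin_ma = 0.1,
    ltr_model = "JC69"
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) {
    rlang::abort(paste0("invalid config key(s): ", paste(bad, collapse = ", "),
                        "; valid keys: ", paste(names(cfg), collapse = ", ")),
                 class = "wgdclock_config_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

.need_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    rlang::abort(paste0("missing upstream artifact '", basename(path),
                        "': run the '", producer, "' stage first"),
                 class = "wgdclock_dependency_error")
  }
  path
}

.stage_log <- function(msg) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), msg)
}

#' Run pipeline stages on a directory of inputs
#'
#' Stages: `simulate` (write synthetic inputs into `indir`), `kaks`,
#' `ksdist`, `fitpeaks`, `date`, `ltrage`, `goaccel`, `teprox`, or
#' `all` (everything after `simulate` in dependency order). Each stage
#' reads its inputs from `indir` or from an upstream stage's TSV in
#' `outdir` and writes a TSV with a commented metadata block; a
#' `manifest.json` (parameters, seed, per-stage row counts, md5
#' checksums) is written at the end. Reruns with the same config and
#' seed reproduce identical numeric outputs.
#'
#' @param stage One of the stage names above.
#' @param indir Input directory (synthetic or real annotations).
#' @param outdir Output directory.
#' @param config A [pipeline_config()].
#' @param sim_config A [simulation_config()] (used by `simulate`).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(stage = "all", indir, outdir,
                         config = pipeline_config(),
                         sim_config = simulation_config(config$seed)) {
  stages <- c("simulate", "kaks", "ksdist", "fitpeaks", "date",
              "ltrage", "goaccel", "teprox", "all")
  if (!stage %in% stages) {
    rlang::abort(paste0("unknown stage '", stage, "'; valid: ",
                        paste(stages, collapse = ", ")),
                 class = "wgdclock_config_error")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  todo <- if (stage == "all") stages[2:8] else stage
  manifest <- list(seed = config$seed,
                   parameters = unclass(config)[-1],
                   stages = list())
  meta <- list(seed = config$seed)

  for (st in todo) {
    .stage_log(paste("stage", st))
    rows <- switch(
      st,
      simulate = {
        simulate_dataset(sim_config, indir)
        length(list.files(indir))
      },
      kaks = {
        pairs <- read_paired_fasta(.need_artifact(
          file.path(indir, "genes.fasta"), "simulate"))
        res <- kaks(pairs)
        write_stage_tsv(res, file.path(outdir, "kaks.tsv"), meta)
        nrow(res)
      },
      ksdist = {
        anchors <- read_anchors(.need_artifact(
          file.path(indir, "anchors.tsv"), "simulate"))
        if (!"ks" %in% names(anchors)) {
          kk <- read_stage_tsv(.need_artifact(
            file.path(outdir, "kaks.tsv"), "kaks"))
          anchors <- attach_ks(anchors, kk)
        }
        med <- block_median_ks(anchors, min_pairs = config$min_pairs,
                               ks_max = config$ks_max)
        write_stage_tsv(med, file.path(outdir, "blocks.tsv"),
                        c(meta, min_pairs = config$min_pairs))
        nrow(med)
      },
      fitpeaks = {
        med <- read_stage_tsv(.need_artifact(
          file.path(outdir, "blocks.tsv"), "ksdist"))
        fit <- fit_ks_peaks(med, k = config$k, window = config$ks_window,
                            seed = config$seed)
        out <- tidy(fit)
        out$n <- fit$n_values
        out$k <- fit$k
        out$bic <- fit$bic
        write_stage_tsv(out, file.path(outdir, "peaks.tsv"), meta)
        nrow(out)
      },
      date = {
        pk <- read_stage_tsv(.need_artifact(
          file.path(outdir, "peaks.tsv"), "fitpeaks"))
        ech <- max(pk$mean)
        younger <- sort(pk$mean[pk$mean < ech])
        peaks <- stats::setNames(
          c(younger, ech),
          c(paste0("WGD", seq_along(younger)), "ECH"))
        dated <- date_peaks(peaks, k_focal_ech = ech, cal = config$cal)
        write_stage_tsv(dated, file.path(outdir, "dating.tsv"), meta)
        nrow(dated)
      },
      ltrage = {
        ltr <- read_ltr_fasta(.need_artifact(
          file.path(indir, "ltr_pairs.fasta"), "simulate"))
        prof <- insertion_time_profile(ltr, mu = config$mu,
                                       bin_width_ma = config$ltr_bin_ma,
                                       model = config$ltr_model)
        ages <- prof$ages
        ages$t_ma <- insertion_time(ifelse(is.na(ages$k), NA_real_, ages$k),
                                    config$mu)
        write_stage_tsv(
          ages[, c("element_id", "superfamily", "p", "k", "t_ma", "flags")],
          file.path(outdir, "ltr_ages.tsv"),
          c(meta, mu = config$mu, model = config$ltr_model))
        write_stage_tsv(prof$histogram, file.path(outdir, "ltr_hist.tsv"),
                        meta)
        nrow(ages)
      },
      goaccel = {
        kk <- read_stage_tsv(.need_artifact(
          file.path(outdir, "kaks.tsv"), "kaks"))
        g2g <- read_gene2go(.need_artifact(
          file.path(indir, "gene2go.tsv"), "simulate"))
        kk$gene <- kk$id_a
        res <- category_test(kk, g2g, min_orthologs = config$min_orthologs)
        write_stage_tsv(res, file.path(outdir, "go_accel.tsv"), meta)
        nrow(res)
      },
      teprox = {
        genes <- read_gene_gff(.need_artifact(
          file.path(indir, "genes.gff3"), "simulate"))
        tes <- read_te_bed(.need_artifact(
          file.path(indir, "tes.bed"), "simulate"))
        dist <- nearest_gene_distance(genes, tes)
        write_stage_tsv(dist, file.path(outdir, "te_distance.tsv"), meta)
        tst <- proximity_test(dist, bin_edge_bp = config$bin_edge_bp)
        write_stage_tsv(tst$tests, file.path(outdir, "te_tests.tsv"),
                        c(meta, bin_edge_bp = config$bin_edge_bp))
        nrow(dist)
      })
    manifest$stages[[st]] <- list(rows = rows)
  }
  outs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(outs))
  names(manifest$checksums) <- basename(outs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
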