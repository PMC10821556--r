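#' Run the full glycomics analysis pipeline
#'
#' Sequences the stages end to end: read per-spot peak CSVs, internally
#' recalibrate against the library m/z values, annotate with
#' signal-to-noise filtering (noise estimated from unassigned peaks),
#' total-area normalize, average replicates, compute derived traits, run
#' the per-trait group comparison report, the trait-wise pairwise ROC/AUC
#' panel, PCA, LDA (cancer vs benign) and — when a discovery/validation
#' split column is present — the three-class random-forest evaluation with
#' feature importances. All tables are written as TSV when `out_dir` is
#' given, and the run is deterministic under `seed`.
#'
#' @param peaks_dir Directory of `{sample}_{replicate}.csv` peak tables.
#' @param metadata Metadata tibble or TSV path: `sample_id`, `diagnosis`
#'   (`normal`/`benign`/`cancer`), optionally `split`
#'   (`discovery`/`validation`) and clinical covariates.
#' @param library_path Glycan library TSV; `NULL` for the shipped default.
#' @param out_dir Optional output directory for TSV reports.
#' @param ann_config An [annotation_config()].
#' @param mass_cfg A [mass_config()].
#' @param ntree,folds Random-forest evaluation parameters.
#' @param seed Integer seed (forests, fold assignment).
#' @return A list bundle: `profiles`, `traits`, `stats_report`,
#'   `roc_panel`, `pca`, `lda`, `rf` (discovery CV, or `NULL`),
#'   `rf_validation` (validation AUC report, or `NULL`).
#' @export
run_pipeline <- function(peaks_dir, metadata, library_path = NULL,
                         out_dir = NULL,
                         ann_config = annotation_config(),
                         mass_cfg = mass_config(),
                         ntree = 500, folds = 5, seed = 1) {
  if (is.character(metadata)) {
    metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
  }
  stopifnot(all(c("sample_id", "diagnosis") %in% names(metadata)))
  if (length(unique(metadata$diagnosis)) < 2) {
    stop("metadata must contain at least two diagnosis groups", call. = FALSE)
  }
  lib <- glycan_library(library_path, mass_cfg)
  peaks <- read_peaklists(peaks_dir)
  missing_samples <- setdiff(metadata$sample_id, unique(peaks$sample_id))
  if (length(missing_samples) > 0) {
    stop("no peak files for sample(s): ",
      paste(utils::head(missing_samples, 5), collapse = ", "),
      call. = FALSE
    )
  }
  message(
    "pipeline: ", length(unique(peaks$sample_id)), " samples, ",
    nrow(lib), " library glycans, tolerance ", ann_config$tolerance,
    " Da, seed ", seed
  )

  peaks <- recalibrate_peaks(peaks, lib$mz, ann_config)
  noise <- estimate_noise(peaks, lib$mz, ann_config$tolerance)
  profiles <- peaks |>
    annotate_peaks(lib, ann_config, noise = noise) |>
    normalize_profile() |>
    average_replicates()
  traits <- compute_traits(profiles, lib)

  md <- metadata[match(traits$sample_id, metadata$sample_id), ]
  stats_report <- trait_group_report(traits, md, diagnosis)

  groups <- sort(unique(md$diagnosis))
  pair_grid <- utils::combn(groups, 2)
  trait_cols <- trait_names()
  roc_panel <- purrr::map_dfr(seq_len(ncol(pair_grid)), function(i) {
    a <- pair_grid[1, i]
    b <- pair_grid[2, i]
    keep <- md$diagnosis %in% c(a, b)
    purrr::map_dfr(trait_cols, function(tr) {
      tibble::tibble(
        group_a = a, group_b = b, trait = tr,
        auc = roc_auc(traits[[tr]][keep], md$diagnosis[keep] == b)
      )
    })
  })

  pca <- pca_project(traits[, c("sample_id", trait_cols)], groups = md$diagnosis)
  lda <- NULL
  if (all(c("benign", "cancer") %in% md$diagnosis)) {
    keep <- md$diagnosis %in% c("benign", "cancer")
    lda <- lda_project(
      traits[keep, c("sample_id", trait_cols)],
      md$diagnosis[keep]
    )
  }

  rf <- NULL
  rf_validation <- NULL
  if ("split" %in% names(md) && length(unique(md$diagnosis)) == 3) {
    disc <- md$split == "discovery"
    rf <- rf_multiclass_cv(traits[disc, trait_cols], md$diagnosis[disc],
      ntree = ntree, folds = folds, seed = seed
    )
    if (any(md$split == "validation")) {
      fit <- ranger::ranger(
        x = as.data.frame(traits[disc, trait_cols]),
        y = factor(md$diagnosis[disc]),
        num.trees = ntree, probability = TRUE, seed = seed, num.threads = 1
      )
      val <- md$split == "validation"
      pv <- stats::predict(fit, as.data.frame(traits[val, trait_cols]),
        num.threads = 1
      )$predictions
      rf_validation <- multiclass_auc(pv, md$diagnosis[val])
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(profile_matrix(profiles), file.path(out_dir, "profile_matrix.tsv"))
    readr::write_tsv(traits, file.path(out_dir, "traits.tsv"))
    readr::write_tsv(stats_report, file.path(out_dir, "stats_report.tsv"))
    readr::write_tsv(roc_panel, file.path(out_dir, "roc_auc_panel.tsv"))
    readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"))
    if (!is.null(lda)) readr::write_tsv(lda$scores, file.path(out_dir, "lda_scores.tsv"))
    if (!is.null(rf)) {
      readr::write_tsv(rf$importance, file.path(out_dir, "rf_importance.tsv"))
      readr::write_tsv(glance(rf), file.path(out_dir, "rf_report.tsv"))
    }
  }

  list(
    profiles = profiles, traits = traits, stats_report = stats_report,
    roc_panel = roc_panel, pca = pca, lda = lda,
    rf = rf, rf_validation = rf_validation,
    config = list(
      ann_config = ann_config, ntree = ntree, folds = folds,
      seed = seed, noise = noise
    )
  )
}
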