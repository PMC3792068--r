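# Autodetect comma vs tab delimiter from a header line.
detect_delim <- function(header_line) {
  if (grepl(",", header_line, fixed = TRUE)) "," else "\t"
}

#' Read a glycan abundance matrix
#'
#' Delimited text (comma-separated, with a tab-separated fallback
#' autodetected from the header): first column sample IDs, remaining
#' columns one glycan each, named by composition code (`5402`) or integer
#' peak label (`2378`) — both resolve to the same panel column. Values are
#' abundances in pmol/uL and must be non-negative numbers.
#'
#' @param path Input file path.
#' @param panel Panel used to validate glycan identifiers (default
#'   [reference_panel()]); pass `NULL` to skip identifier validation.
#' @return A tibble with a `sample_id` column plus one numeric column per
#'   glycan, headers as in the file.
#' @export
read_abundance_matrix <- function(path, panel = reference_panel()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("Abundance matrix needs a header and at least one sample row.")
  delim <- detect_delim(lines[1])
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- trimws(fields[[1]])
  ncol_expected <- length(header)
  for (i in seq_along(fields)[-1]) {
    if (length(fields[[i]]) != ncol_expected) {
      abort(paste0("Ragged abundance matrix: line ", i, " has ",
                   length(fields[[i]]), " fields, expected ", ncol_expected, "."))
    }
  }
  glycans <- header[-1]
  if (anyDuplicated(glycans)) {
    abort(paste0("Duplicate glycan columns: ",
                 paste(unique(glycans[duplicated(glycans)]), collapse = ", "), "."))
  }
  body <- do.call(rbind, fields[-1])
  sample_id <- trimws(body[, 1])
  if (anyDuplicated(sample_id)) {
    abort(paste0("Duplicate sample IDs: ",
                 paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "), "."))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(body[, -1, drop = FALSE]), nrow = nrow(body))
  )
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("Non-numeric abundance for sample ", sample_id[bad[1, 1]],
                 ", glycan ", glycans[bad[1, 2]], "."))
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(paste0("Negative abundance for sample ", sample_id[neg[1, 1]],
                 ", glycan ", glycans[neg[1, 2]], "."))
  }
  colnames(vals) <- glycans
  out <- dplyr::bind_cols(tibble(sample_id = sample_id), as_tibble(vals))
  if (!is.null(panel)) resolve_glycan_columns(out, panel) # errors on unknowns
  out
}

#' Write an abundance matrix
#'
#' @param abundance Wide abundance tibble (`sample_id` + glycan columns).
#' @param path Output path (CSV).
#' @export
write_abundance_matrix <- function(abundance, path) {
  readr::write_csv(abundance, path)
  invisible(abundance)
}

#' Read a sample metadata table
#'
#' Delimited text with a `sample_id` column and typed clinical columns
#' (`group`, `cai`, `mayo`, `extent`, `steroid_refractory`, `time_months`,
#' `event`, ...). Columns required by a downstream analysis are checked by
#' that analysis; `require` lets the caller insist up front.
#'
#' @param path Input file path.
#' @param require Character vector of column names that must be present.
#' @return A typed tibble.
#' @export
read_metadata <- function(path, require = character(0)) {
  header <- readLines(path, n = 1)
  delim <- detect_delim(header)
  md <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!"sample_id" %in% names(md)) abort("Metadata must have a `sample_id` column.")
  missing_cols <- setdiff(require, names(md))
  if (length(missing_cols) > 0) {
    abort(paste0("Metadata lacks required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  typed <- list(
    sample_id = as.character, group = as.character, cai = as.integer,
    mayo = as.integer, extent = as.character,
    steroid_refractory = as.logical, marker_high = as.logical,
    severity = as.numeric, time_months = as.numeric, event = as.integer
  )
  for (col in intersect(names(typed), names(md))) {
    md[[col]] <- typed[[col]](md[[col]])
  }
  as_tibble(md)
}

#' @rdname read_metadata
#' @param metadata Metadata tibble.
#' @param path Output path (CSV).
#' @export
write_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path)
  invisible(metadata)
}

# Abundance/metadata sample IDs must match exactly; report set differences.
check_sample_alignment <- function(abundance, metadata) {
  extra_ab <- setdiff(abundance$sample_id, metadata$sample_id)
  extra_md <- setdiff(metadata$sample_id, abundance$sample_id)
  if (length(extra_ab) > 0 || length(extra_md) > 0) {
    abort(paste0(
      "Sample ID mismatch between abundance matrix and metadata. ",
      if (length(extra_ab) > 0) {
        paste0("Only in abundance: ", paste(extra_ab, collapse = ", "), ". ")
      } else "",
      if (length(extra_md) > 0) {
        paste0("Only in metadata: ", paste(extra_md, collapse = ", "), ".")
      } else ""
    ))
  }
  metadata[match(abundance$sample_id, metadata$sample_id), , drop = FALSE]
}

#' Pipeline configuration
#'
#' @param abundance_path,metadata_path Input file paths (CSV/TSV).
#' @param out_dir Output directory for the report bundle (created if
#'   needed; the pipeline writes nowhere else).
#' @param alpha Family-wise error rate for the Bonferroni screen, in (0,1).
#' @param entry_p Univariate-to-multivariate Cox entry threshold.
#' @param B Bootstrap resamples (>= 100).
#' @param seed Integer seed governing all pipeline randomness.
#' @param cutoff_q Quantile for marker dichotomization (0.5 = median).
#' @param collinearity_r Multivariate collinearity exclusion threshold.
#' @param case,control Group labels.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance_path, metadata_path, out_dir,
                            alpha = 0.05, entry_p = 0.1, B = 10000,
                            seed = 1, cutoff_q = 0.5, collinearity_r = 0.7,
                            case = "UC", control = "HLT") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(B) || B < 100) abort("`B` must be at least 100.")
  if (!is.numeric(entry_p) || entry_p <= 0 || entry_p > 1) {
    abort("`entry_p` must lie in (0, 1].")
  }
  structure(
    list(
      abundance_path = abundance_path, metadata_path = metadata_path,
      out_dir = out_dir, alpha = alpha, entry_p = entry_p, B = as.integer(B),
      seed = as.integer(seed), cutoff_q = cutoff_q,
      collinearity_r = collinearity_r, case = case, control = control
    ),
    class = "pipeline_config"
  )
}

# Run one pipeline stage, prefixing any error with the stage name.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the whole-serum glycomics pipeline end to end
#'
#' Classify the panel, screen per-glycan differences with Bonferroni
#' control, select the up/down ratio marker, export the annotated
#' biosynthesis network, compare the marker and the highly sialylated
#' multi-branched aggregate across clinical strata with seeded bootstraps,
#' and run the prognostic survival analysis (Kaplan-Meier + log-rank,
#' univariate Cox screen, multivariate Cox with collinearity exclusion,
#' cut-off sensitivity/specificity). All report tables are written under
#' `config$out_dir` together with a plain-text run log; a rerun with the
#' same config and seed reproduces every report byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the in-memory results (`panel`,
#'   `differential`, `marker`, `class_summary`, `strata`, `bootstrap`,
#'   `km`, `logrank`, `cox_univariate`, `cox_multivariate`, `accuracy`,
#'   `paths`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be built with pipeline_config().")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  panel <- reference_panel()

  abundance <- run_stage("read",
    read_abundance_matrix(config$abundance_path, panel))
  metadata <- run_stage("read", {
    md <- read_metadata(config$metadata_path, require = "group")
    check_sample_alignment(abundance, md)
  })

  cls <- run_stage("classify",
    write_classification_report(panel, out("panel_classification.csv")))

  diff <- run_stage("differential", {
    d <- differential_expression(abundance, metadata$group,
                                 case = config$case, control = config$control,
                                 alpha = config$alpha, panel = panel)
    readr::write_csv(d, out("differential.csv"))
    d
  })

  marker <- run_stage("ratio-marker", {
    m <- select_ratio_marker(diff, abundance, metadata$group,
                             case = config$case, control = config$control,
                             panel = panel)
    readr::write_csv(tidy(m), out("marker_samples.csv"))
    readr::write_csv(glance(m), out("marker_summary.csv"))
    m
  })

  net_summary <- run_stage("pathway", {
    g <- build_network(panel)
    g <- annotate_fold_change(g, abundance, metadata$group,
                              case = config$case, control = config$control,
                              panel = panel)
    export_graph(g, out("network.graphml"), format = "graphml")
    export_graph(g, out("network.sif"), format = "sif")
    cs <- class_summary(g)
    readr::write_csv(cs, out("class_summary.csv"))
    cs
  })

  boot <- run_stage("bootstrap", {
    purrr::map_dfr(c("complex", "sialylated"), function(cl) {
      agg <- aggregate_abundance(abundance, cl, panel)
      bs <- bootstrap_group_means(agg$abundance, metadata$group,
                                  B = config$B, seed = config$seed)
      dplyr::mutate(bs$estimates, class = cl, p_boot = bs$p,
                    .before = 1)
    }) -> b
    readr::write_csv(b, out("bootstrap_group_means.csv"))
    b
  })

  uc <- metadata$group == config$case
  uc_md <- metadata[uc, , drop = FALSE]
  marker_uc <- marker$ratios[marker$ratios$group == config$case, ]
  marker_uc <- marker_uc[match(uc_md$sample_id, marker_uc$sample_id), ]

  strata <- run_stage("strata", {
    s <- compare_strata(marker_uc$ratio, uc_md, B = config$B,
                        seed = config$seed)
    readr::write_csv(s, out("strata_marker.csv"))
    s
  })

  surv_res <- run_stage("survival", {
    hs <- aggregate_abundance(abundance[uc, , drop = FALSE],
                              "highly_sialylated_multibranched", panel)
    d <- tibble(
      sample_id = uc_md$sample_id,
      time_months = uc_md$time_months,
      event = uc_md$event,
      marker_ratio_high = as.numeric(dichotomize(marker_uc$ratio,
                                                 config$cutoff_q)),
      hs_glycans_high = as.numeric(dichotomize(hs$abundance, config$cutoff_q)),
      cai_high = as.numeric(uc_md$cai > 10),
      mayo3 = as.numeric(uc_md$mayo == 3),
      steroid_refractory = as.numeric(uc_md$steroid_refractory)
    )
    km <- km_estimate(dplyr::mutate(d, group = ifelse(
      marker_ratio_high == 1, "high", "low")), group = "group")
    readr::write_csv(as_tibble(km), out("km_curve.csv"))
    lr <- logrank_test(dplyr::mutate(d, group = ifelse(
      marker_ratio_high == 1, "high", "low")), group = "group")
    readr::write_csv(glance(lr), out("logrank.csv"))

    covs <- c("marker_ratio_high", "hs_glycans_high", "cai_high",
              "mayo3", "steroid_refractory")
    uni <- univariate_screen(d, covs, entry_p = config$entry_p)
    readr::write_csv(uni, out("cox_univariate.csv"))
    selected <- uni$term[uni$selected]
    multi <- NULL
    if (length(selected) >= 2) {
      cont <- tibble(
        marker_ratio_high = marker_uc$ratio,
        hs_glycans_high = hs$abundance,
        cai_high = as.numeric(uc_md$cai),
        mayo3 = as.numeric(uc_md$mayo),
        steroid_refractory = as.numeric(uc_md$steroid_refractory)
      )
      multi <- multivariate_cox(d, selected,
                                collinearity_r = config$collinearity_r,
                                collinearity_data = cont)
      readr::write_csv(tidy(multi), out("cox_multivariate.csv"))
    } else if (length(selected) == 1) {
      multi <- cox_fit(d, selected)
      readr::write_csv(tidy(multi), out("cox_multivariate.csv"))
    }
    acc <- diagnostic_accuracy(d$marker_ratio_high == 1, d$event)
    readr::write_csv(acc, out("marker_accuracy.csv"))
    list(km = km, logrank = lr, uni = uni, multi = multi, acc = acc)
  })

  run_stage("log", {
    log_lines <- c(
      "glycoprof pipeline run",
      paste0("package_version: ",
             as.character(utils::packageVersion("glycoprof"))),
      paste0("seed: ", config$seed),
      paste0("alpha: ", config$alpha),
      paste0("entry_p: ", config$entry_p),
      paste0("bootstrap_B: ", config$B),
      paste0("cutoff_q: ", config$cutoff_q),
      paste0("collinearity_r: ", config$collinearity_r),
      paste0("case: ", config$case, "  control: ", config$control),
      paste0("n_samples: ", nrow(abundance)),
      paste0("n_glycans: ", nrow(panel)),
      paste0("marker: ", marker$numerator$code, "/", marker$denominator$code,
             "  auroc: ", format(marker$auroc, digits = 6))
    )
    writeLines(log_lines, out("run_log.txt"))
  })

  invisible(list(
    panel = cls, differential = diff, marker = marker,
    class_summary = net_summary, bootstrap = boot, strata = strata,
    km = surv_res$km, logrank = surv_res$logrank,
    cox_univariate = surv_res$uni, cox_multivariate = surv_res$multi,
    accuracy = surv_res$acc,
    paths = list.files(config$out_dir, full.names = TRUE)
  ))
}
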