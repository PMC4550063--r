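# Guideline configuration: loading, structural validation.
#
# The engine is agnostic to the numbers in the pre-test-probability table and
# the band cut-points; everything ships in an editable YAML file and only the
# structural invariants below are enforced, at load time rather than at use
# time:
#   * investigation bands partition [0, 100] exactly (no gap, no overlap),
#     half-open [lo, hi) with the top band closed at 100;
#   * the PTP table is total over sex x age band x typicality x risk level;
#   * for fixed (sex, age band, typicality): PTP(high risk) >= PTP(low risk);
#   * for fixed (sex, age band, risk): typical >= atypical >= non-anginal.

#' Path to the packaged default guideline configuration
#'
#' The packaged file transcribes the NICE CG95 pre-test-probability table and
#' investigation bands, plus a documented stand-in for the expert panel's
#' medication rules.
#'
#' @return file path of the packaged YAML config.
#' @export
default_guideline_path <- function() {
  system.file("extdata", "guideline_nice_cg95.yaml", package = "anginacdss",
              mustWork = TRUE)
}

#' Load and validate a guideline configuration
#'
#' Reads a YAML guideline file (sections `ptp_table`, `age_bands`,
#' `investigation_bands`, `medication_rules`, `panel_threshold`, and
#' optionally `risk_flags`) and checks every structural invariant. Violations
#' are rejected here, naming the offending intervals or table cells, so the
#' decision engine can assume a coherent config.
#'
#' @param path YAML file path; defaults to the packaged NICE CG95 config.
#' @return a validated `guideline_config` list.
#' @export
#' @examples
#' cfg <- load_guideline_config()
#' cfg$panel_threshold
load_guideline_config <- function(path = default_guideline_path()) {
  if (!file.exists(path)) {
    cdss_abort(paste0("guideline config not found: ", path), "cdss_config_error")
  }
  raw <- yaml::read_yaml(path)
  validate_guideline_config(raw)
}

#' Validate an in-memory guideline configuration
#'
#' @param raw a list with the structure of the packaged YAML file.
#' @return the config, classed `guideline_config`, if every invariant holds.
#' @export
validate_guideline_config <- function(raw) {
  for (section in c("ptp_table", "age_bands", "investigation_bands",
                    "medication_rules", "panel_threshold")) {
    if (is.null(raw[[section]])) {
      cdss_abort(paste0("guideline config missing section: ", section),
                 "cdss_config_error")
    }
  }

  edges <- raw$age_bands$edges
  labels <- raw$age_bands$labels
  if (is.unsorted(edges, strictly = TRUE) || length(labels) != length(edges) + 1) {
    cdss_abort("age_bands: edges must be strictly increasing with one more label than edge",
               "cdss_config_error")
  }

  # --- investigation bands partition [0, 100] ---
  bands <- raw$investigation_bands
  lo <- vapply(bands, function(b) as.numeric(b$lo), numeric(1))
  hi <- vapply(bands, function(b) as.numeric(b$hi), numeric(1))
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  bad <- which(hi <= lo)
  if (length(bad) > 0) {
    cdss_abort(paste0("investigation_bands: empty or inverted interval(s): ",
                      paste(sprintf("[%g,%g)", lo[bad], hi[bad]), collapse = ", ")),
               "cdss_config_error")
  }
  if (lo[1] != 0 || hi[length(hi)] != 100) {
    cdss_abort("investigation_bands: bands must start at 0 and end at 100",
               "cdss_config_error")
  }
  if (length(lo) > 1) {
    gaps <- which(hi[-length(hi)] < lo[-1])
    overlaps <- which(hi[-length(hi)] > lo[-1])
    if (length(gaps) > 0) {
      cdss_abort(paste0("investigation_bands: gap between ",
                        paste(sprintf("[%g,%g) and [%g,%g)",
                                      lo[gaps], hi[gaps], lo[gaps + 1], hi[gaps + 1]),
                              collapse = "; ")),
                 "cdss_config_error")
    }
    if (length(overlaps) > 0) {
      cdss_abort(paste0("investigation_bands: overlap between ",
                        paste(sprintf("[%g,%g) and [%g,%g)",
                                      lo[overlaps], hi[overlaps],
                                      lo[overlaps + 1], hi[overlaps + 1]),
                              collapse = "; ")),
                 "cdss_config_error")
    }
  }
  band_names <- vapply(bands, function(b) b$name, character(1))[ord]
  invs <- vapply(bands, function(b) b$investigation, character(1))[ord]
  if (!all(invs %in% INVESTIGATIONS)) {
    cdss_abort("investigation_bands: unknown investigation name", "cdss_config_error")
  }

  # --- PTP table totality and monotonicity ---
  ptp <- raw$ptp_table
  missing_cells <- character(0)
  for (sx in SEX_LEVELS) {
    for (ab in labels) {
      for (ty in TYPICALITY_LEVELS) {
        for (rk in RISK_LEVELS) {
          v <- ptp[[sx]][[ab]][[ty]][[rk]]
          if (is.null(v) || !is.numeric(v) || v < 0 || v > 100) {
            missing_cells <- c(missing_cells, paste(sx, ab, ty, rk, sep = "/"))
          }
        }
      }
    }
  }
  if (length(missing_cells) > 0) {
    cdss_abort(paste0("ptp_table not total: missing or invalid cell(s): ",
                      paste(missing_cells, collapse = ", ")),
               "cdss_config_error")
  }
  non_mono <- character(0)
  for (sx in SEX_LEVELS) {
    for (ab in labels) {
      for (ty in TYPICALITY_LEVELS) {
        cell <- ptp[[sx]][[ab]][[ty]]
        if (cell$high < cell$low) {
          non_mono <- c(non_mono, paste(sx, ab, ty, "high<low", sep = "/"))
        }
      }
      for (rk in RISK_LEVELS) {
        v <- vapply(TYPICALITY_LEVELS, function(ty) ptp[[sx]][[ab]][[ty]][[rk]],
                    numeric(1))
        if (v["typical"] < v["atypical"] || v["atypical"] < v["non_anginal"]) {
          non_mono <- c(non_mono, paste(sx, ab, rk,
                                        "typicality order violated", sep = "/"))
        }
      }
    }
  }
  if (length(non_mono) > 0) {
    cdss_abort(paste0("ptp_table monotonicity violated: ",
                      paste(non_mono, collapse = "; ")),
               "cdss_config_error")
  }

  # --- medication rules total over typicality x band, <= 3 classes ---
  bad_rules <- character(0)
  for (ty in TYPICALITY_LEVELS) {
    for (bn in band_names) {
      classes <- raw$medication_rules[[ty]][[bn]]
      if (is.null(classes)) {
        # distinguish a genuinely missing key from an empty class list
        if (!bn %in% names(raw$medication_rules[[ty]] %||% list())) {
          bad_rules <- c(bad_rules, paste(ty, bn, sep = "/"))
          next
        }
        classes <- character(0)
      }
      classes <- as.character(unlist(classes))
      if (!all(classes %in% MED_CLASSES) || length(unique(classes)) > 3) {
        bad_rules <- c(bad_rules, paste(ty, bn, sep = "/"))
      }
    }
  }
  if (length(bad_rules) > 0) {
    cdss_abort(paste0("medication_rules not total or invalid for: ",
                      paste(bad_rules, collapse = ", ")),
               "cdss_config_error")
  }

  thr <- raw$panel_threshold
  if (!is.numeric(thr) || thr < 0 || thr > 100) {
    cdss_abort("panel_threshold must be a percent in [0, 100]", "cdss_config_error")
  }

  risk_flags <- unlist(raw$risk_flags %||%
                         list("smoker", "diabetes", "hyperlipidaemia", "ecg_abnormal"))
  allowed_flags <- c("smoker", "diabetes", "hyperlipidaemia", "ecg_abnormal")
  if (!all(risk_flags %in% allowed_flags)) {
    cdss_abort("risk_flags must be drawn from smoker/diabetes/hyperlipidaemia/ecg_abnormal",
               "cdss_config_error")
  }

  structure(
    list(
      age_band_edges = as.numeric(edges),
      age_band_labels = labels,
      ptp_table = ptp,
      investigation_bands = tibble::tibble(
        name = band_names, lo = lo, hi = hi, investigation = invs
      ),
      medication_rules = raw$medication_rules,
      panel_threshold = as.numeric(thr),
      risk_flags = as.character(risk_flags)
    ),
    class = "guideline_config"
  )
}

#' @export
print.guideline_config <- function(x, ...) {
  cat("<guideline_config>\n")
  cat("  age bands:", paste(x$age_band_labels, collapse = ", "), "\n")
  cat("  investigation bands:\n")
  with(x$investigation_bands,
       cat(sprintf("    [%3g, %3g%s %s\n", lo, hi,
                   ifelse(hi == 100, "]", ")"), investigation), sep = ""))
  cat("  panel threshold: >", x$panel_threshold, "% -> invasive_angiography\n")
  cat("  risk flags:", paste(x$risk_flags, collapse = ", "), "\n")
  invisible(x)
}
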