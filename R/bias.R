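#' Thresholds for the diagnostic-bias rules
#'
#' The bias taxonomy is verbal ("accuracy close to the majority-count ratio",
#' "imbalanced sensitivity and specificity"); these numeric defaults encode
#' those phrases and are calibrated so the published benchmark patterns
#' classify correctly. All are configurable.
#'
#' @param delta_spec Specificity ceiling for the overfitting rule (0.05).
#' @param delta_acc Margin above the majority ratio separating "accuracy at
#'   or below the deceptive floor" (explicit skew) from "accuracy above it"
#'   (implicit skew). The default 0.025 is the value that separates the
#'   published explicit rows (accuracy gaps between -0.029 and +0.023) from
#'   the implicit one (+0.0275).
#' @param delta_rand Half-width of "near-chance accuracy" around 0.5 (0.1).
#' @param delta_gap Minimum sensitivity-specificity gap that counts as
#'   imbalanced (0.30).
#' @return A list of thresholds (class `bias_thresholds`).
#' @export
bias_thresholds <- function(delta_spec = 0.05, delta_acc = 0.025,
                            delta_rand = 0.1, delta_gap = 0.30) {
  structure(list(delta_spec = delta_spec, delta_acc = delta_acc,
                 delta_rand = delta_rand, delta_gap = delta_gap),
            class = "bias_thresholds")
}

#' Classify the diagnostic bias of an evaluation run
#'
#' Rule cascade over the aggregated metrics, the label distribution, and the
#' Gram-matrix structure:
#' \enumerate{
#'   \item identity-like Gram, specificity at (near) zero, and accuracy at the
#'     majority-count ratio: \strong{overfitting} -- the kernel cannot see any
#'     similarity between distinct samples, so every test sample falls back to
#'     the intercept, i.e. the majority vote.
#'   \item flat (constant) Gram and near-chance accuracy:
#'     \strong{underfitting} -- the kernel cannot distinguish samples at all.
#'   \item normal Gram, accuracy at or below the majority ratio (within
#'     `delta_acc` above it), imbalanced sensitivity/specificity:
#'     \strong{explicit label skew} -- the accuracy is the majority-count
#'     floor in disguise.
#'   \item normal Gram, accuracy more than `delta_acc` above the majority
#'     ratio but still imbalanced sensitivity/specificity:
#'     \strong{implicit label skew} -- the deceptive case whose accuracy
#'     looks healthy.
#'   \item otherwise \strong{none}.
#' }
#'
#' @param metrics Named list or one-row data frame with `accuracy`,
#'   `sensitivity`, `specificity` as fractions (means over folds).
#' @param counts A [label_counts()] for the evaluated dataset.
#' @param gram_structure `"identity_like"`, `"flat_like"`, or `"normal"`
#'   (from [classify_gram()] on the training Gram).
#' @param alpha_report Optional [signed_alpha_report()] attached as evidence.
#' @param thresholds A [bias_thresholds()].
#' @return A `bias_report`: `bias_type` plus an `evidence` list
#'   (gram structure, majority ratio, accuracy gap, sensitivity-specificity
#'   gap, alpha sign counts, bias sign, beta).
#' @export
classify_bias <- function(metrics, counts, gram_structure,
                          alpha_report = NULL,
                          thresholds = bias_thresholds()) {
  acc <- as.numeric(metrics$accuracy %||% metrics[["accuracy"]])
  sens <- as.numeric(metrics$sensitivity)
  spec <- as.numeric(metrics$specificity)
  ratio <- majority_ratio(counts)
  th <- thresholds
  acc_gap <- acc - ratio
  ss_gap <- abs(sens - spec)
  bias_type <-
    if (gram_structure == "identity_like" &&
        isTRUE(spec <= th$delta_spec) &&
        isTRUE(abs(acc_gap) <= th$delta_acc)) {
      "overfitting"
    } else if (gram_structure == "flat_like" &&
               isTRUE(acc <= 0.5 + th$delta_rand)) {
      "underfitting"
    } else if (gram_structure == "normal" &&
               isTRUE(acc_gap <= th$delta_acc) &&
               isTRUE(ss_gap >= th$delta_gap)) {
      "explicit_label_skew"
    } else if (gram_structure == "normal" &&
               isTRUE(acc_gap > th$delta_acc) &&
               isTRUE(ss_gap >= th$delta_gap)) {
      "implicit_label_skew"
    } else {
      "none"
    }
  beta <- if (!is.nan(sens) && !is.nan(spec) && acc > 0) {
    diagnostic_index(acc, sens, spec)
  } else NaN
  structure(
    list(bias_type = bias_type,
         evidence = list(
           gram_structure = gram_structure,
           majority_ratio = ratio,
           accuracy_gap_to_majority = acc_gap,
           sens_spec_gap = ss_gap,
           alpha_sign_counts = if (is.null(alpha_report)) NULL else
             c(positive = alpha_report$n_positive_sign,
               negative = alpha_report$n_negative_sign),
           bias_sign = if (is.null(alpha_report)) NULL else
             alpha_report$bias_sign,
           beta = beta),
         thresholds = th),
    class = "bias_report"
  )
}

#' @export
print.bias_report <- function(x, ...) {
  ev <- x$evidence
  cat("<bias_report> ", x$bias_type, "\n", sep = "")
  cat("  gram: ", ev$gram_structure,
      " | majority ratio: ", sprintf("%.4f", ev$majority_ratio),
      " | acc gap: ", sprintf("%+.4f", ev$accuracy_gap_to_majority),
      " | sens-spec gap: ", format_nan(ev$sens_spec_gap), "\n", sep = "")
  if (!is.null(ev$alpha_sign_counts)) {
    cat("  alpha signs: ", ev$alpha_sign_counts[["positive"]], " positive / ",
        ev$alpha_sign_counts[["negative"]], " negative; b sign ",
        c("-", "0", "+")[ev$bias_sign + 2], "\n", sep = "")
  }
  cat("  diagnostic index beta: ", format_nan(ev$beta, 4), "\n", sep = "")
  invisible(x)
}

format_nan <- function(v, digits = 4) {
  if (is.nan(v)) return("NaN")
  if (abs(v) < 0.5 * 10^-digits) v <- 0  # avoid printing negative zero
  sprintf(paste0("%.", digits, "f"), v)
}

#' Render a bias report as structured text
#'
#' @param report A `bias_report`.
#' @param path Output path.
#' @return `report`, invisibly.
#' @export
write_bias_report <- function(report, path) {
  stopifnot(inherits(report, "bias_report"))
  con <- file(path, "w")
  on.exit(close(con))
  ev <- report$evidence
  lines <- c(
    paste0("bias_type\t", report$bias_type),
    paste0("gram_structure\t", ev$gram_structure),
    paste0("majority_ratio\t", sprintf("%.6f", ev$majority_ratio)),
    paste0("accuracy_gap_to_majority\t",
           sprintf("%.6f", ev$accuracy_gap_to_majority)),
    paste0("sens_spec_gap\t", format_nan(ev$sens_spec_gap, 6)),
    paste0("beta\t", format_nan(ev$beta, 4))
  )
  if (!is.null(ev$alpha_sign_counts)) {
    lines <- c(lines,
               paste0("alpha_positive_signs\t", ev$alpha_sign_counts[["positive"]]),
               paste0("alpha_negative_signs\t", ev$alpha_sign_counts[["negative"]]),
               paste0("bias_sign\t", ev$bias_sign))
  }
  writeLines(lines, con)
  invisible(report)
}
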