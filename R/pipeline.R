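## End-to-end orchestration: candidate generation by parental subtraction,
## then per-candidate window extraction, evidence summarization and
## classification (CNN model bank or the rule-based caller).

#' Validate a run configuration
#'
#' @param threshold de novo probability threshold in `[0, 1]`.
#' @param mode `"WES"` or `"WGS"`.
#' @param rule_based use the rule-based caller instead of the CNN?
#' @return a validated `run_config` list.
#' @export
run_config <- function(threshold = 0.5, mode = c("WES", "WGS"),
                       rule_based = FALSE) {
  mode <- match.arg(mode)
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1) {
    stop2("threshold must be a number in [0, 1]")
  }
  list(threshold = threshold, mode = mode, rule_based = rule_based)
}

#' Call de novo mutations in a trio
#'
#' Step one discards child variants present in either parent's VCF
#' (allele-aware subtraction). Step two extracts the trio read window for
#' each surviving candidate, summarizes the per-member evidence, and
#' labels the candidate: with `rule_based = TRUE` the deterministic
#' parental-evidence caller decides; otherwise the candidate image is
#' classified by the per-variant-type CNN bank and thresholded at
#' `threshold` (inclusive). Hard-filter verdicts (population-AF pre-filter
#' and high-quality post-filter) are reported alongside.
#'
#' @param trio a [load_trio()] object.
#' @param models named list of trained `dnm_cnn` models per variant type
#'   (ignored when `rule_based = TRUE`).
#' @param rule_based use the rule-based caller.
#' @param threshold CNN probability threshold (default 0.5, inclusive).
#' @param mode `"WES"` or `"WGS"` (population-AF pre-filter preset).
#' @param af_table optional data.frame (contig, position, ref, alt,
#'   population_af[, caller_quality]) with population annotations.
#' @param intensity an [intensity_model()].
#' @return data.frame with one row per candidate: contig, position, ref,
#'   alt, variant_type, per-member depth/alt/vaf, p_dnm (NA for
#'   rule-based), label (`"DNM"`/`"IV"`), filter reason columns.
#' @export
dnm_call <- function(trio, models = NULL, rule_based = FALSE,
                     threshold = 0.5, mode = c("WES", "WGS"),
                     af_table = NULL, intensity = intensity_model()) {
  mode <- match.arg(mode)
  cfg <- run_config(threshold, mode, rule_based)
  candidates <- subtract_inherited(trio)
  n <- nrow(candidates)
  message(sprintf("candidates after parental subtraction: %d (%s)", n,
                  paste(names(table(candidates$variant_type)),
                        table(candidates$variant_type),
                        sep = ":", collapse = ", ")))
  out <- candidates
  cols <- c("depth_child", "depth_father", "depth_mother",
            "alt_child", "alt_father", "alt_mother", "vaf_child",
            "p_dnm", "label", "denovo_filter", "af_prefilter", "hq_filter")
  for (cl in cols) out[[cl]] <- rep(NA, n)
  out$label <- rep(NA_character_, n)
  if (n == 0L) return(out)
  keys <- variant_key(candidates)
  af_lookup <- NULL
  if (!is.null(af_table)) {
    af_lookup <- stats::setNames(af_table$population_af,
                                 variant_key(af_table))
  }
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    window <- tryCatch(
      extract_trio_window(trio, cand$contig, cand$position,
                          cand$ref, cand$alt),
      error = function(e) stop2("site ", keys[i], ": ", conditionMessage(e))
    )
    af <- if (!is.null(af_lookup) && keys[i] %in% names(af_lookup)) {
      af_lookup[[keys[i]]]
    } else {
      NA_real_
    }
    ev <- genotype_evidence(window, population_af = af)
    out$depth_child[i] <- ev$depth[["child"]]
    out$depth_father[i] <- ev$depth[["father"]]
    out$depth_mother[i] <- ev$depth[["mother"]]
    out$alt_child[i] <- ev$alt_reads[["child"]]
    out$alt_father[i] <- ev$alt_reads[["father"]]
    out$alt_mother[i] <- ev$alt_reads[["mother"]]
    out$vaf_child[i] <- ev$vaf[["child"]]
    dn <- inhouse_denovo_filter(ev)
    out$denovo_filter[i] <- dn$reason
    out$af_prefilter[i] <- population_af_prefilter(ev, mode)$reason
    out$hq_filter[i] <- high_quality_filter(ev)$reason
    if (rule_based) {
      out$label[i] <- if (dn$pass) "DNM" else "IV"
    } else {
      if (is.null(models)) stop2("models required unless rule_based = TRUE")
      img <- encode_trio(window, intensity)
      res <- classify_dnm(models, img, threshold)
      out$p_dnm[i] <- res$p_dnm
      out$label[i] <- res$label
    }
  }
  message(sprintf("labelled DNM: %d / %d candidates",
                  sum(out$label == "DNM"), n))
  out
}

#' Train the per-variant-type model bank
#'
#' Trains the substitution model from random initialization first, then
#' warm-starts the insertion and deletion models from its weights (AdamW
#' with weight decay for the indel models, Adam for substitutions). Types
#' absent from the dataset are skipped with a warning.
#'
#' @param dataset list with `x` (image array), `y` (0/1 labels) and
#'   `variant_type`, as returned by [encode_dataset()].
#' @param config a [model_config()].
#' @param training a [training_config()] (optimizer field is set per
#'   model).
#' @param val_fraction fraction of each type's images held out for
#'   validation.
#' @return named list of trained `dnm_cnn` models.
#' @export
train_dnm_models <- function(dataset, config = model_config(),
                             training = training_config(),
                             val_fraction = 0.15) {
  types <- c("substitution", "insertion", "deletion")
  bank <- list()
  sub_model <- NULL
  for (vt in types) {
    idx <- which(dataset$variant_type == vt)
    if (length(idx) < 10L || length(unique(dataset$y[idx])) < 2L) {
      warning("too few ", vt, " examples; skipping that model",
              call. = FALSE)
      next
    }
    set.seed(training$seed)
    n_val <- max(1L, floor(length(idx) * val_fraction))
    val <- sample(idx, n_val)
    tr <- setdiff(idx, val)
    model <- build_network(config, seed = training$seed)
    tc <- training
    if (vt == "substitution") {
      tc$optimizer <- "adam"
    } else {
      tc$optimizer <- "adamw"
      if (!is.null(sub_model)) model <- warm_start(model, sub_model)
    }
    fit <- train_cnn(model,
                     dataset$x[, , , tr, drop = FALSE], dataset$y[tr],
                     dataset$x[, , , val, drop = FALSE], dataset$y[val],
                     tc)
    if (vt == "substitution") sub_model <- fit
    bank[[vt]] <- fit
  }
  bank
}

#' Save / load a model bank
#'
#' Checkpoints are written as one JSON sidecar (configuration, history)
#' plus a flat parameter dump per model, all plain text.
#'
#' @param bank named list of `dnm_cnn` models.
#' @param dir checkpoint directory.
#' @return `save_model_bank`: the directory, invisibly;
#'   `load_model_bank`: the model bank.
#' @export
save_model_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (vt in names(bank)) {
    model <- bank[[vt]]
    jsonlite::write_json(
      list(config = unclass(model$config), history = model$history,
           best_epoch = model$best_epoch),
      file.path(dir, paste0(vt, ".json")), auto_unbox = TRUE, digits = NA)
    theta <- unlist(model$params, use.names = FALSE)
    writeLines(format(theta, digits = 17),
               file.path(dir, paste0(vt, ".weights.txt")))
  }
  invisible(dir)
}

#' @rdname save_model_bank
#' @export
load_model_bank <- function(dir) {
  jsons <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  bank <- list()
  for (js in jsons) {
    vt <- sub("\\.json$", "", basename(js))
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
    cfg <- do.call(model_config, c(
      meta$config[c("conv_layers", "filters", "se_every", "se_ratio", "l1")],
      list(input_shape = c(meta$config$rows, meta$config$cols,
                           meta$config$channels))))
    model <- build_network(cfg, seed = 1L)
    theta <- as.numeric(readLines(file.path(dir, paste0(vt, ".weights.txt"))))
    model$params <- utils::relist(theta, model$params)
    model$history <- meta$history
    model$best_epoch <- meta$best_epoch
    model$trained <- TRUE
    bank[[vt]] <- model
  }
  bank
}
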