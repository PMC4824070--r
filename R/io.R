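# Shared CSV/JSON readers and writers. CSV dialect: comma-separated, UTF-8,
# '.' decimal, '#'-prefixed metadata header lines.

.meta_lines <- function(seed = NULL, params = list()) {
  lines <- c(
    sprintf("# tool: termeff %s", as.character(utils::packageVersion("termeff")))
  )
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (length(params) > 0) {
    lines <- c(lines, sprintf("# %s: %s", names(params),
                              vapply(params, function(p) paste(format(p), collapse = ","), "")))
  }
  lines
}

#' Read a plate-reader measurements table
#'
#' Long-format CSV with columns `construct_id`, `replicate`, `time_min`,
#' `od600`, `f_rfp`, `f_gfp` (extra columns pass through; `#` lines are
#' metadata comments). Rows are grouped by construct and replicate and sorted
#' by time, so row order in the file does not matter. Invariants are
#' validated with offending rows named: positive OD, non-negative
#' fluorescence, strictly increasing time within each replicate.
#'
#' @param path CSV path.
#' @return A validated measurements tibble sorted by construct, replicate,
#'   time.
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("construct_id", "replicate", "time_min", "od600", "f_rfp", "f_gfp")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  bad_od <- which(is.na(df$od600) | df$od600 <= 0)
  if (length(bad_od) > 0) {
    abort(sprintf("invalid OD: non-positive od600 at data row(s) %s",
                  paste(utils::head(bad_od, 5), collapse = ", ")))
  }
  bad_f <- which(df$f_rfp < 0 | df$f_gfp < 0)
  if (length(bad_f) > 0) {
    abort(sprintf("negative fluorescence at data row(s) %s",
                  paste(utils::head(bad_f, 5), collapse = ", ")))
  }
  df <- dplyr::arrange(df, .data$construct_id, .data$replicate, .data$time_min)
  dup <- df |>
    dplyr::group_by(.data$construct_id, .data$replicate) |>
    dplyr::filter(duplicated(.data$time_min)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0) {
    abort(sprintf("time not strictly increasing for construct %s replicate %s",
                  dup$construct_id[1], format(dup$replicate[1])))
  }
  df
}

#' Read a construct table
#'
#' CSV with columns `construct_id`, `series`, `distance_nt`, `rfp_modified`,
#' `translation_coupled`, `is_reference` (logical columns accept TRUE/FALSE
#' or 0/1). Exactly one reference row is required.
#'
#' @param path CSV path.
#' @return A constructs tibble.
#' @export
read_construct_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("construct_id", "series", "distance_nt", "rfp_modified",
           "translation_coupled", "is_reference")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  for (col in c("rfp_modified", "translation_coupled", "is_reference")) {
    df[[col]] <- as.logical(df[[col]])
  }
  if (sum(df$is_reference) != 1) {
    abort("construct table must contain exactly one reference row.")
  }
  df
}

#' Write a TE table with a metadata header
#'
#' @param te_table A TE tibble (e.g. from [quantify_te()] or
#'   [make_te_table()]).
#' @param path Output CSV path.
#' @param seed Seed recorded in the metadata header, if any.
#' @param params Named list of extra metadata recorded as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_te_table <- function(te_table, path, seed = NULL, params = list()) {
  writeLines(.meta_lines(seed, params), path)
  readr::write_csv(te_table, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TE table written by [write_te_table()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_te_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write a coupling-model fit to JSON
#'
#' Serializes the fitted parameters, objective value and any bootstrap
#' intervals, with tool version (and seed, when given) in a metadata block.
#' Reals survive a JSON round trip to full double precision.
#'
#' @param fit A `te_fit` from [fit_coupling()].
#' @param path Output JSON path.
#' @param seed Seed recorded in the metadata block, if any.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "te_fit"))
  obj <- list(
    metadata = list(
      tool = paste("termeff", as.character(utils::packageVersion("termeff"))),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    te0 = fit$params$te0,
    alpha = fit$params$alpha,
    offsets = as.list(fit$params$offsets),
    cdf_convention = fit$params$cdf_convention,
    rss = fit$rss,
    n_points = fit$n_points,
    weights = fit$weights
  )
  if (!is.null(fit$bootstrap)) {
    obj$bootstrap_ci <- lapply(seq_len(nrow(fit$bootstrap)), function(i) {
      list(term = fit$bootstrap$term[i],
           conf_low = fit$bootstrap$conf.low[i],
           conf_high = fit$bootstrap$conf.high[i])
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read fitted coupling parameters from JSON
#'
#' @param path JSON path written by [write_fit()].
#' @return A list with `params` (a [coupling_params()]) and `rss`.
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    params = coupling_params(
      te0 = obj$te0, alpha = obj$alpha,
      offsets = unlist(obj$offsets),
      cdf_convention = obj$cdf_convention
    ),
    rss = obj$rss
  )
}

#' Write simulator samples to CSV
#'
#' @param samples A `sim_samples` tibble from [simulate_coupling()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_samples <- function(samples, path) {
  cfg <- attr(samples, "config")
  params <- if (!is.null(cfg)) {
    list(distance_nt = cfg$distance_nt, te0 = cfg$te0, alpha = cfg$alpha,
         k_rnap = cfg$k_rnap, k_ribosome = cfg$k_ribosome, k_init = cfg$k_init)
  } else {
    list()
  }
  writeLines(.meta_lines(attr(samples, "seed"), params), path)
  readr::write_csv(tibble::as_tibble(samples), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}
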