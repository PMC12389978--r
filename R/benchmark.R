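# Sampling-rate sweeps and report generation.

#' Run a sampling-rate sweep over reconstruction pipelines
#'
#' Executes every requested pipeline at every rate/seed combination and
#' returns one tidy row per run, in deterministic (algorithm, rate, seed)
#' order. Individual pipeline failures are captured in the row's `status`
#' column and the sweep continues.
#'
#' @param img Grayscale image matrix in \[0, 1\].
#' @param algorithms Subset of `c("dwt", "fft", "dct", "bp")`.
#' @param rates Sampling rates in (0, 1\]; default is the 35--75% grid in
#'   5-point steps.
#' @param seeds Integer seeds; each stochastic pipeline runs once per seed
#'   (the deterministic DCT pipeline runs once per rate regardless, with the
#'   first seed recorded).
#' @param bp_size Side length for the basis-pursuit pipeline resize.
#' @param ssim_window SSIM window mode (see [ssim()]).
#' @return A `cs_sweep` tibble: columns `algorithm`, `label`, `rate`, `seed`,
#'   `status`, then the metric columns of [metrics_report()].
#' @export
cs_sweep <- function(img, algorithms = c("dwt", "fft", "dct", "bp"),
                     rates = seq(0.35, 0.75, by = 0.05), seeds = 1L,
                     bp_size = 128, ssim_window = "gaussian") {
  assert_image(img)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  stopifnot(length(rates) > 0, all(rates > 0), all(rates <= 1),
            length(seeds) > 0)
  grid <- tidyr::expand_grid(
    algorithm = intersect(c("dwt", "fft", "dct", "bp"), algorithms),
    rate = sort(rates),
    seed = as.integer(seeds)
  ) |>
    dplyr::filter(!(.data$algorithm == "dct" & .data$seed != seeds[[1]]))
  rows <- purrr::pmap(grid, function(algorithm, rate, seed) {
    res <- tryCatch(
      switch(algorithm,
        dwt = run_dwt_pipeline(img, rate, seed, ssim_window = ssim_window),
        fft = run_fft_pipeline(img, rate, seed, ssim_window = ssim_window),
        dct = run_dct_pipeline(img, rate, ssim_window = ssim_window),
        bp = run_bp_pipeline(img, rate, seed, size = bp_size,
                             ssim_window = ssim_window)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(algorithm = algorithm, label = NA_character_,
                     rate = rate, seed = seed,
                     status = paste("error:", conditionMessage(res)))
    } else {
      row <- tidy(res)
      row$seed <- seed
      row
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cs_sweep", class(out))
  out
}

#' Min-max normalize a data series to \[0, 1\]
#'
#' `(v - min) / (max - min)`, the normalization applied to metric curves
#' before comparative plotting. A constant series maps to all zeros.
#' Idempotent and order-preserving.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_series <- function(values) {
  stopifnot(is.numeric(values), length(values) > 0)
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(rep(0, length(values)))
  (values - lo) / (hi - lo)
}

#' Write sweep results to disk
#'
#' Materializes a sweep as plain-text artifacts: the raw rows
#' (`sweep_raw.csv`), per-algorithm normalized RMSE/PSNR/data-loss curves
#' indexed both by sampling rate and by compression efficiency
#' (`sweep_normalized.csv`), and a short text summary (`summary.txt`). CSVs
#' are comma-separated with period decimals and LF line endings, so reruns
#' are byte-identical.
#'
#' @param table A `cs_sweep` tibble.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(table, out_dir) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  raw_path <- file.path(out_dir, "sweep_raw.csv")
  norm_path <- file.path(out_dir, "sweep_normalized.csv")
  summary_path <- file.path(out_dir, "summary.txt")

  fmt <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) {
      out <- formatC(v, digits = 10, format = "g")
      out[is.infinite(v) & v > 0] <- "inf"
      out[is.infinite(v) & v < 0] <- "-inf"
      out[is.na(v)] <- "NA"
      out
    })
    df
  }
  con <- file(raw_path, open = "wb")
  write.csv(fmt(table), con, row.names = FALSE, quote = FALSE)
  close(con)

  ok <- table[!startsWith(table$status %||% "ok", "error"), , drop = FALSE]
  curves <- ok |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::arrange(.data$rate, .by_group = TRUE) |>
    dplyr::reframe(
      rate = .data$rate,
      compression_efficiency = .data$compression_efficiency,
      rmse_norm = normalize_series(.data$rmse),
      psnr_norm = normalize_series(replace(.data$psnr_db,
                                           is.infinite(.data$psnr_db),
                                           max(.data$psnr_db[is.finite(.data$psnr_db)],
                                               0))),
      data_loss_norm = normalize_series(.data$data_loss_pct)
    )
  con <- file(norm_path, open = "wb")
  write.csv(fmt(curves), con, row.names = FALSE, quote = FALSE)
  close(con)

  lines <- c(
    "Sampling-rate sweep summary",
    sprintf("rows: %d; algorithms: %s", nrow(table),
            paste(unique(table$algorithm), collapse = ", ")),
    sprintf("rates: %s", paste(format(sort(unique(table$rate))), collapse = ", ")),
    "",
    utils::capture.output(print(as.data.frame(
      ok |>
        dplyr::group_by(.data$algorithm) |>
        dplyr::summarise(
          mean_psnr_db = mean(.data$psnr_db[is.finite(.data$psnr_db)]),
          mean_ssim = mean(.data$ssim),
          mean_data_loss_pct = mean(.data$data_loss_pct),
          .groups = "drop"
        )
    )))
  )
  writeLines(lines, summary_path)
  invisible(c(raw_path, norm_path, summary_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname cs_sweep
#' @param object A `cs_sweep` tibble.
#' @param metric One of `"psnr_db"`, `"rmse"`, `"ssim"`, `"data_loss_pct"`.
#' @param ... Unused.
#' @method autoplot cs_sweep
#' @export
autoplot.cs_sweep <- function(object, metric = "psnr_db", ...) {
  stopifnot(metric %in% c("psnr_db", "rmse", "ssim", "data_loss_pct"))
  df <- object[is.finite(object[[metric]]), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$rate, .data[[metric]],
                                   colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sampling rate", y = metric,
                  title = "Reconstruction quality vs sampling rate")
}
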