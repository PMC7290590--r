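#' Discard equilibration frames
#'
#' Drops, independently for every (replicate, replica) series, the first
#' `ceiling(fraction * n)` records in step order.  Mirrors the practice of
#' discarding the initial equilibration segment of each constant-pH run
#' before computing insertion-resolved statistics.
#'
#' @param records insertion-record (or frame) data.frame with columns
#'   `replicate_id`, `replica_id`, `step`.
#' @param fraction fraction of initial frames to drop, in `[0, 1)`.
#' @return the trimmed data.frame.
#' @export
discard_burn_in <- function(records, fraction) {
  if (fraction < 0 || fraction >= 1)
    stop_config("burn-in fraction must be in [0, 1)")
  if (fraction == 0 || !nrow(records)) return(records)
  dt <- data.table::as.data.table(records)
  data.table::setorder(dt, replicate_id, replica_id, step)
  keep <- dt[, .I[seq_len(.N) > ceiling(fraction * .N)],
             by = .(replicate_id, replica_id)]$V1
  out <- as.data.frame(dt[sort(keep)])
  rownames(out) <- NULL
  out
}

#' Bin insertion records along the membrane normal
#'
#' Assigns every record to the half-open depth bin `[d_lo, d_hi)` containing
#' its insertion depth `d`, using uniform bins of width `bin_width` anchored
#' at `origin`, and summarises each (bin, pH, replicate) cell by its mean
#' protonation and frame count.  Records outside `d_range` are dropped and
#' counted.
#'
#' @param records insertion records (see [compute_insertion()]).
#' @param bin_width bin width in Angstrom (default 1).
#' @param d_range optional length-2 numeric range; records with `d` outside
#'   it are dropped.  Default covers all records.
#' @param origin bin-grid anchor (default 0): bin k spans
#'   `[origin + k*w, origin + (k+1)*w)`.
#' @return an object of class `insertion_bins`: a data.frame of cells with
#'   columns `bin_index`, `d_lo`, `d_hi`, `d_center`, `pH`, `replicate_id`,
#'   `mean_prot`, `n_frames`; attributes `bin_width`, `origin`, `n_dropped`.
#' @export
bin_records <- function(records, bin_width = 1.0, d_range = NULL, origin = 0) {
  if (bin_width <= 0) stop_config("bin_width must be > 0")
  if (!nrow(records)) stop_data("no records to bin")
  n_in <- nrow(records)
  if (!is.null(d_range)) {
    records <- records[records$d >= d_range[1] & records$d <= d_range[2], ,
                       drop = FALSE]
  }
  n_dropped <- n_in - nrow(records)
  if (n_dropped > 0)
    message(n_dropped, " record(s) outside d_range dropped")
  if (!nrow(records)) stop_data("no records inside d_range")
  dt <- data.table::as.data.table(records)
  dt[, bin_index := as.integer(floor((d - origin) / bin_width))]
  cells <- dt[, .(mean_prot = mean(prot_state), n_frames = .N),
              by = .(bin_index, pH, replicate_id)]
  cells[, `:=`(d_lo = origin + bin_index * bin_width,
               d_hi = origin + (bin_index + 1) * bin_width,
               d_center = origin + (bin_index + 0.5) * bin_width)]
  data.table::setorder(cells, bin_index, pH, replicate_id)
  out <- as.data.frame(cells[, .(bin_index, d_lo, d_hi, d_center, pH,
                                 replicate_id, mean_prot, n_frames)])
  attr(out, "bin_width") <- bin_width
  attr(out, "origin") <- origin
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("insertion_bins", "data.frame")
  out
}

#' Pool a bin's cells into a titration curve
#'
#' Per-pH pooled mean protonation with, by default, equal weight per
#' replicate (a replicate's mean counts once regardless of how many frames it
#' contributed); `weights = "frame"` pools frame-weighted instead.  The
#' protonation error is the standard error of the mean across replicate
#' means.
#'
#' @param cells data.frame of one bin's cells (`pH`, `replicate_id`,
#'   `mean_prot`, `n_frames`).
#' @param weights `"replicate"` (default) or `"frame"`.
#' @return a data.frame with `pH`, `prot` (pooled mean), `sem`,
#'   `n_replicates`, sorted by pH.
#' @export
titration_curve <- function(cells, weights = c("replicate", "frame")) {
  weights <- match.arg(weights)
  dt <- data.table::as.data.table(cells)
  cur <- if (weights == "replicate") {
    dt[, .(prot = mean(mean_prot),
           sem = if (.N > 1) stats::sd(mean_prot) / sqrt(.N) else NA_real_,
           n_replicates = .N), by = pH]
  } else {
    dt[, .(prot = sum(mean_prot * n_frames) / sum(n_frames),
           sem = if (.N > 1) stats::sd(mean_prot) / sqrt(.N) else NA_real_,
           n_replicates = .N), by = pH]
  }
  data.table::setorder(cur, pH)
  as.data.frame(cur)
}

#' Sample-quality status of one insertion bin
#'
#' Applies the per-bin gating criteria required before a Henderson-
#' Hasselbalch fit is attempted: the bin must hold average protonation values
#' at two or more distinct pH values, contributed by two or more distinct
#' replicates, and the pooled per-pH mean protonation must not increase with
#' pH (non-strict monotonicity; ties pass, increases beyond
#' `monotonic_tolerance` fail).
#'
#' @param cells data.frame of one bin's cells.
#' @param min_pH minimum distinct pH values (default 2).
#' @param min_replicates minimum distinct replicates (default 2).
#' @param monotonic_tolerance allowed increase of pooled protonation between
#'   adjacent pH values (default 0).
#' @param weights pooling mode passed to [titration_curve()].
#' @return one of `"ok"`, `"insufficient_pH"`, `"insufficient_replicates"`,
#'   `"non_monotonic"`.
#' @export
bin_quality <- function(cells, min_pH = 2L, min_replicates = 2L,
                        monotonic_tolerance = 0,
                        weights = c("replicate", "frame")) {
  if (!nrow(cells)) stop_data("bin has no cells")
  if (length(unique(cells$pH)) < min_pH) return("insufficient_pH")
  if (length(unique(cells$replicate_id)) < min_replicates)
    return("insufficient_replicates")
  cur <- titration_curve(cells, weights)
  if (nrow(cur) > 1 && any(diff(cur$prot) > monotonic_tolerance))
    return("non_monotonic")
  "ok"
}

#' Fit the Henderson-Hasselbalch equation to a titration curve
#'
#' Least-squares estimate of the single parameter pKa in
#' `prot(pH) = 1 / (1 + 10^(pH - pKa))` (fixed Hill coefficient 1).  A single
#' point with protonation strictly inside (0, 1) is solved in closed form,
#' `pKa = pH + log10(x / (1 - x))`.  Otherwise the squared loss is scanned on
#' a 0.05-unit grid over `[min(pH) - 5, max(pH) + 5]` (the coarse scan plays
#' the role of the 0.5-crossing initial guess: it brackets the global
#' minimum) and refined with [stats::optimize()].  An estimate pinned to the
#' search boundary is reported as a failed fit.
#'
#' @param curve data.frame with columns `pH` and `prot` (pooled mean
#'   protonation), e.g. from [titration_curve()].
#' @return a list with `pka` (numeric or `NA`), `status` (`"ok"` or
#'   `"fit_failed"`) and `sse`.
#' @examples
#' hh <- function(pH, pka) 1 / (1 + 10^(pH - pka))
#' fit_hh(data.frame(pH = 8:10, prot = hh(8:10, 9)))$pka
#' @export
fit_hh <- function(curve) {
  pH <- curve$pH
  y <- curve$prot
  if (!length(pH)) stop_data("empty titration curve")
  if (length(pH) == 1) {
    if (y > 0 && y < 1)
      return(list(pka = pH + log10(y / (1 - y)), status = "ok", sse = 0))
    return(list(pka = NA_real_, status = "fit_failed", sse = NA_real_))
  }
  lo <- min(pH) - 5
  hi <- max(pH) + 5
  sse <- function(k) {
    r <- y - 1 / (1 + 10^(pH - k))
    sum(r * r)
  }
  grid <- seq(lo, hi, by = 0.05)
  vals <- vapply(grid, sse, 0)
  k0 <- grid[which.min(vals)]
  opt <- stats::optimize(sse, lower = max(lo, k0 - 0.1),
                         upper = min(hi, k0 + 0.1), tol = 1e-9)
  pka <- opt$minimum
  if (!is.finite(pka) || pka < lo + 0.1 || pka > hi - 0.1)
    return(list(pka = NA_real_, status = "fit_failed", sse = NA_real_))
  list(pka = pka, status = "ok", sse = opt$objective)
}

#' Bayesian-bootstrap standard error of a bin's pKa
#'
#' Resamples the bin's per-(pH, replicate) mean-protonation cells with
#' continuous Dirichlet(1, ..., 1) weights (one weight per cell per
#' bootstrap), forms weighted per-pH mean protonation curves, re-applies the
#' monotonicity quality criterion (the pH- and replicate-coverage criteria
#' are unaffected by strictly positive weights), refits the
#' Henderson-Hasselbalch equation, and reports the standard deviation of the
#' retained pKa estimates.  Bootstraps failing the criteria or the fit are
#' dropped and counted.
#'
#' @param cells data.frame of one bin's cells.
#' @param B number of bootstraps (default 1000).
#' @param seed integer seed; the same seed reproduces the SE exactly.
#' @param monotonic_tolerance passed to the monotonicity gate.
#' @return a list with `se`, `n_retained`, `n_dropped` and `pka` (the vector
#'   of retained bootstrap estimates).
#' @export
bayesian_bootstrap_pka <- function(cells, B = 1000L, seed = 1L,
                                   monotonic_tolerance = 0) {
  status <- bin_quality(cells, monotonic_tolerance = monotonic_tolerance)
  if (status != "ok")
    stop_data(paste0("bin must pass quality gating before bootstrapping (",
                     status, ")"))
  n <- nrow(cells)
  pHs <- sort(unique(cells$pH))
  groups <- lapply(pHs, function(p) which(cells$pH == p))
  prot <- cells$mean_prot
  withr::with_seed(as.integer(seed), {
    W <- matrix(stats::rexp(B * n), nrow = B)
    curves <- vapply(groups, function(g) {
      as.numeric(W[, g, drop = FALSE] %*% prot[g]) /
        rowSums(W[, g, drop = FALSE])
    }, numeric(B))
    if (B == 1) curves <- matrix(curves, nrow = 1)
    mono_ok <- apply(curves, 1, function(v) all(diff(v) <= monotonic_tolerance))
    pka <- rep(NA_real_, B)
    for (b in which(mono_ok)) {
      f <- fit_hh(data.frame(pH = pHs, prot = curves[b, ]))
      if (f$status == "ok") pka[b] <- f$pka
    }
  })
  keep <- !is.na(pka)
  if (!any(keep)) stop_data("bin not bootstrappable")
  list(se = if (sum(keep) > 1) stats::sd(pka[keep]) else 0,
       n_retained = sum(keep), n_dropped = B - sum(keep), pka = pka[keep])
}

#' Build insertion-resolved protonation, abundance, charge and pKa profiles
#'
#' Composes the full post-processing chain on a table of insertion records:
#' burn-in removal, depth binning, per-bin quality gating, per-bin
#' Henderson-Hasselbalch fits with Bayesian-bootstrap standard errors, plus
#' per-pH abundance histograms (normalised over bins) and mean-charge
#' profiles (charge equals the protonation state for a monovalent base).
#' Positive depths are the membrane-internal region below the phosphate
#' plane.
#'
#' @param records insertion records from [compute_insertion()].
#' @param config optional [sim_config()] supplying `burn_in_fraction` and the
#'   bootstrap seed.
#' @param bin_width depth bin width in Angstrom (default 1).
#' @param burn_in burn-in fraction (default from `config`, else 0.5).
#' @param bootstraps Bayesian bootstraps per ok bin (default 1000).
#' @param seed bootstrap base seed (default from `config`, else 1).
#' @param d_range optional depth range; records outside are dropped.
#' @param monotonic_tolerance monotonicity gate tolerance.
#' @param weights pooling mode, `"replicate"` (default) or `"frame"`.
#' @return an object of class `pka_profile_set`: a list with
#'   * `pka_profile`: per-bin `d_center`, `status`, `n_frames`, `pka`,
#'     `bootstrap_se`, `boot_retained`, `boot_dropped`;
#'   * `abundance`: per (pH, bin) frame counts and fractions summing to 1
#'     per pH;
#'   * `charge`: per (bin, pH) pooled mean charge;
#'   * `curves`: per-bin titration curves (`pH`, `prot`, `sem`,
#'     `n_replicates`);
#'   * `cells`: the gated bin cells;
#'   * `params`: bin width, burn-in, bootstrap count, seed, dropped counts.
#' @export
build_profiles <- function(records, config = NULL, bin_width = 1.0,
                           burn_in = NULL, bootstraps = 1000L, seed = NULL,
                           d_range = NULL, monotonic_tolerance = 0,
                           weights = c("replicate", "frame")) {
  weights <- match.arg(weights)
  if (!nrow(records)) stop_data("no insertion records supplied")
  if (is.null(burn_in))
    burn_in <- if (!is.null(config)) config$burn_in_fraction else 0.5
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else 1L
  n_input <- nrow(records)
  records <- discard_burn_in(records, burn_in)
  if (!nrow(records)) stop_data("no records left after burn-in")
  cells <- bin_records(records, bin_width = bin_width, d_range = d_range)
  cdt <- data.table::as.data.table(cells)

  # per-bin gating + HH fit + bootstrap SE
  bins <- sort(unique(cdt$bin_index))
  prof <- data.frame(bin_index = bins,
                     d_center = attr(cells, "origin") +
                       (bins + 0.5) * attr(cells, "bin_width"),
                     status = NA_character_, n_frames = NA_integer_,
                     pka = NA_real_, bootstrap_se = NA_real_,
                     boot_retained = NA_integer_, boot_dropped = NA_integer_,
                     stringsAsFactors = FALSE)
  curves_list <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    bc <- as.data.frame(cdt[bin_index == bins[i]])
    prof$n_frames[i] <- sum(bc$n_frames)
    st <- bin_quality(bc, monotonic_tolerance = monotonic_tolerance,
                      weights = weights)
    cur <- titration_curve(bc, weights)
    curves_list[[i]] <- data.frame(bin_index = bins[i],
                                   d_center = prof$d_center[i], cur)
    if (st == "ok") {
      fit <- fit_hh(cur)
      if (fit$status == "ok") {
        prof$pka[i] <- fit$pka
        bs <- tryCatch(
          bayesian_bootstrap_pka(bc, B = bootstraps,
                                 seed = seed + bins[i] - min(bins),
                                 monotonic_tolerance = monotonic_tolerance),
          memtitrate_data_error = function(e) NULL)
        if (!is.null(bs)) {
          prof$bootstrap_se[i] <- bs$se
          prof$boot_retained[i] <- bs$n_retained
          prof$boot_dropped[i] <- bs$n_dropped
        }
        prof$status[i] <- "ok"
      } else {
        prof$status[i] <- "fit_failed"
      }
    } else {
      prof$status[i] <- st
    }
  }

  # abundance: per pH, fraction of post-burn-in frames in each depth bin
  rdt <- data.table::as.data.table(records)
  rdt[, bin_index := as.integer(floor((d - attr(cells, "origin")) /
                                        attr(cells, "bin_width")))]
  abundance <- rdt[, .(n_frames = .N), by = .(pH, bin_index)]
  abundance[, fraction := n_frames / sum(n_frames), by = pH]
  abundance[, d_center := attr(cells, "origin") +
              (bin_index + 0.5) * attr(cells, "bin_width")]
  data.table::setorder(abundance, pH, bin_index)

  # charge profile: pooled mean protonation per (bin, pH)
  charge <- cdt[, if (weights == "replicate") .(mean_charge = mean(mean_prot))
                else .(mean_charge = sum(mean_prot * n_frames) / sum(n_frames)),
                by = .(bin_index, d_center, pH)]
  data.table::setorder(charge, pH, bin_index)

  structure(list(pka_profile = prof,
                 abundance = as.data.frame(abundance[, .(pH, bin_index,
                                                         d_center, n_frames,
                                                         fraction)]),
                 charge = as.data.frame(charge),
                 curves = do.call(rbind, curves_list),
                 cells = cells,
                 params = list(bin_width = attr(cells, "bin_width"),
                               origin = attr(cells, "origin"),
                               burn_in = burn_in, bootstraps = bootstraps,
                               seed = seed, weights = weights,
                               n_input_records = n_input,
                               n_analysed_records = nrow(records),
                               n_outside_range = attr(cells, "n_dropped"))),
            class = "pka_profile_set")
}

#' @export
print.pka_profile_set <- function(x, ...) {
  p <- x$pka_profile
  cat("<pka_profile_set>", nrow(p), "bins;",
      sum(p$status == "ok"), "ok\n")
  cat("  statuses:", paste(names(table(p$status)), table(p$status),
                           sep = "=", collapse = ", "), "\n")
  ok <- p[p$status == "ok", ]
  if (nrow(ok))
    cat("  pKa range:", sprintf("%.2f..%.2f", min(ok$pka), max(ok$pka)),
        "over d", sprintf("%.1f..%.1f A", min(ok$d_center), max(ok$d_center)),
        "\n")
  invisible(x)
}

#' Write a profile set to TSV tables plus a JSON summary
#'
#' Writes `pka_profile.tsv`, `abundance.tsv`, `charge.tsv`, `curves.tsv` and
#' `summary.json` (statuses, dropped counts, parameters) into a directory.
#'
#' @param profiles a `pka_profile_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  wr(profiles$pka_profile, "pka_profile.tsv")
  wr(profiles$abundance, "abundance.tsv")
  wr(profiles$charge, "charge.tsv")
  wr(profiles$curves, "curves.tsv")
  summary <- list(statuses = as.list(table(profiles$pka_profile$status)),
                  n_bins = nrow(profiles$pka_profile),
                  n_ok = sum(profiles$pka_profile$status == "ok"),
                  params = profiles$params)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
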