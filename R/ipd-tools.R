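#' Digitized Kaplan-Meier curve container
#'
#' Holds coordinates read off a published KM plot together with the
#' numbers-at-risk table printed beneath it, the inputs to
#' [reconstruct_ipd()].  Survival probabilities are monotonized (running
#' minimum) on construction to absorb digitization jitter.
#'
#' @param points Data frame with columns `time` (months, strictly
#'   increasing, first value 0) and `surv` (in `[0, 1]`, first value 1).
#' @param risk_table Data frame with columns `time` and `n_risk`
#'   (non-increasing positive integers); at least two rows.
#' @param total_events Optional total number of events reported by the
#'   trial, used for the reconstruction's final adjustment pass.
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(points, risk_table, total_events = NULL) {
  points <- as.data.frame(points)
  risk_table <- as.data.frame(risk_table)
  stopifnot(all(c("time", "surv") %in% names(points)),
            all(c("time", "n_risk") %in% names(risk_table)))
  if (nrow(risk_table) < 2)
    stop("risk table needs at least two entries", call. = FALSE)
  if (any(diff(points$time) <= 0))
    stop("digitized times must be strictly increasing", call. = FALSE)
  if (points$time[1] != 0 || abs(points$surv[1] - 1) > 1e-8)
    stop("digitized curve must start at (0, 1)", call. = FALSE)
  if (any(points$surv < 0 | points$surv > 1))
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  if (any(diff(risk_table$n_risk) > 0))
    stop("numbers at risk cannot increase over time", call. = FALSE)
  if (any(risk_table$n_risk < 0))
    stop("numbers at risk must be non-negative", call. = FALSE)
  points$surv <- cummin(points$surv)   # isotonic clamp for digitization noise
  structure(list(points = points, risk_table = risk_table,
                 total_events = total_events),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve: %d points to %.1f months, %d risk-table rows%s>\n",
              nrow(x$points), max(x$points$time), nrow(x$risk_table),
              if (is.null(x$total_events)) ""
              else sprintf(", %d total events", x$total_events)))
  invisible(x)
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Implements the iterative reconstruction of Guyot and colleagues: within
#' each interval between consecutive numbers-at-risk, censoring times are
#' spread uniformly and the per-step event counts are solved so that the
#' product-limit estimate of the reconstructed data matches the digitized
#' survival probabilities, then the censoring count is adjusted until the
#' implied number at risk at the start of the next interval equals the
#' published one.  In the final interval the censoring rate is carried over
#' from the earlier intervals; patients still at risk at the last digitized
#' time are administratively censored there, so the record count equals the
#' initial number at risk.  If `total_events` is available a final pass
#' rescales censoring beyond the last event until the event total matches.
#'
#' @param curve A [digitized_curve()].
#' @return Data frame of pseudo-IPD with columns `time` (months) and
#'   `event` (1 = event, 0 = censored); attribute `km_match` records the
#'   largest absolute difference between the digitized probabilities and
#'   the KM estimate of the reconstruction at the digitized times.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  t_s <- curve$points$time
  s <- curve$points$surv
  trisk <- curve$risk_table$time
  nrisk <- curve$risk_table$n_risk
  n_int <- length(trisk)
  n_t <- length(t_s)
  if (max(trisk) > max(t_s)) {
    keep <- trisk <= max(t_s)
    trisk <- trisk[keep]; nrisk <- nrisk[keep]; n_int <- length(trisk)
    if (n_int < 2) stop("risk table does not overlap the digitized window",
                        call. = FALSE)
  }

  # first digitized index of each risk interval; interval i spans
  # clicks lower[i]..upper[i]
  lower <- vapply(trisk, function(x) which(t_s >= x - 1e-9)[1], integer(1))
  if (anyNA(lower)) stop("risk-table time outside the digitized range", call. = FALSE)
  upper <- c(lower[-1] - 1L, n_t)
  if (any(upper < lower))
    stop("risk-table intervals contain no digitized points", call. = FALSE)

  d <- integer(n_t)          # events at each digitized time
  cen <- integer(n_t)        # censorings allocated to each digitized step
  cen_times <- vector("list", n_t)
  n_hat <- numeric(n_t + 1)
  km_hat <- numeric(n_t)
  n_cen_int <- integer(n_int)
  last_idx <- 1L             # index of the last positive-event step

  run_interval <- function(i, n_censor) {
    # allocate n_censor censoring times uniformly over the interval and
    # solve event counts against the digitized KM values; returns updated
    # state for steps lower[i]..upper[i]
    lo <- lower[i]; hi <- upper[i]
    end_t <- if (i < n_int) t_s[lower[i + 1]] else t_s[n_t]
    cen_i <- integer(hi - lo + 1L)
    ct <- numeric(0)
    if (n_censor > 0) {
      ct <- t_s[lo] + seq_len(n_censor) * (end_t - t_s[lo]) / (n_censor + 1)
      # assign each censoring time to the digitized step it falls in
      idx <- findInterval(ct, t_s[lo:min(hi + 1L, n_t)], rightmost.closed = FALSE)
      idx[idx < 1] <- 1L
      idx[idx > (hi - lo + 1L)] <- hi - lo + 1L
      cen_i <- tabulate(idx, nbins = hi - lo + 1L)
    }
    d_i <- integer(hi - lo + 1L)
    km_i <- numeric(hi - lo + 1L)
    nh <- numeric(hi - lo + 2L)
    nh[1] <- nrisk[i]
    last <- last_idx
    km_last <- if (last == 1L && i == 1L) 1 else km_hat[last]
    for (k in lo:hi) {
      j <- k - lo + 1L
      if (i == 1L && k == 1L) {
        d_i[j] <- 0L
        km_i[j] <- 1
      } else {
        d_i[j] <- if (km_last > 0) round(nh[j] * (1 - s[k] / km_last)) else 0L
        d_i[j] <- max(0L, min(d_i[j], nh[j]))
        km_i[j] <- if (nh[j] > 0) km_last * (1 - d_i[j] / nh[j]) else km_last
      }
      nh[j + 1L] <- nh[j] - d_i[j] - cen_i[j]
      if (nh[j + 1L] < 0) {        # cannot censor more than remain at risk
        cen_i[j] <- nh[j] - d_i[j]
        nh[j + 1L] <- 0
      }
      if (d_i[j] > 0) {
        last <- k
        km_last <- km_i[j]
      }
    }
    list(d = d_i, cen = cen_i, km = km_i, n_hat = nh, last = last, cen_t = ct)
  }

  for (i in seq_len(n_int - 1L)) {
    guess <- round(nrisk[i] * s[lower[i + 1L]] / s[lower[i]] - nrisk[i + 1L])
    if (!is.finite(guess)) guess <- 0L   # curve already at zero survival
    n_censor <- max(0L, guess)
    tried <- integer(0)
    repeat {
      res <- run_interval(i, n_censor)
      n_next <- res$n_hat[length(res$n_hat)]
      if (n_next > nrisk[i + 1L]) {
        step <- n_next - nrisk[i + 1L]
      } else if (n_next < nrisk[i + 1L] && n_censor > 0) {
        step <- max(n_next - nrisk[i + 1L], -n_censor)
      } else break
      if (n_censor %in% tried) break   # oscillation: keep the closest state
      tried <- c(tried, n_censor)
      n_censor <- n_censor + step
      if (n_censor > nrisk[i] * 2)
        stop(sprintf("reconstruction failed in interval %d: risk table implies an infeasible censoring count", i),
             call. = FALSE)
    }
    n_next <- res$n_hat[length(res$n_hat)]
    if (n_next < 0)
      stop(sprintf("inconsistent risk table in interval %d: implied negative number at risk", i),
           call. = FALSE)
    if (n_next > nrisk[i + 1L]) {
      # rounding feedback between event counts and spread censorings can
      # leave a residual; close it with administrative censorings at the
      # interval end, which leaves the matched KM steps untouched
      extra <- n_next - nrisk[i + 1L]
      k <- length(res$cen)
      res$cen[k] <- res$cen[k] + extra
      res$cen_t <- c(res$cen_t,
                     rep((t_s[upper[i]] + t_s[lower[i + 1L]]) / 2, extra))
      res$n_hat[length(res$n_hat)] <- nrisk[i + 1L]
      n_next <- nrisk[i + 1L]
    }
    # digitization error can leave fewer at risk than published even with no
    # censoring; the published number is then lowered to the implied one
    if (n_next < nrisk[i + 1L]) nrisk[i + 1L] <- n_next
    lo <- lower[i]; hi <- upper[i]
    d[lo:hi] <- res$d; cen[lo:hi] <- res$cen; km_hat[lo:hi] <- res$km
    n_hat[lo:(hi + 1L)] <- res$n_hat
    n_cen_int[i] <- sum(res$cen)
    cen_times[[i]] <- res$cen_t
    last_idx <- res$last
  }

  # final interval: carry over the average censoring rate seen so far
  i <- n_int
  if (upper[i] >= lower[i]) {
    span_prev <- t_s[lower[n_int]] - t_s[1]
    span_last <- t_s[n_t] - t_s[lower[n_int]]
    rate <- if (span_prev > 0) sum(n_cen_int[seq_len(n_int - 1L)]) / span_prev else 0
    n_censor <- min(nrisk[i], max(0L, round(rate * span_last)))
    res <- run_interval(i, n_censor)
    lo <- lower[i]; hi <- upper[i]
    d[lo:hi] <- res$d; cen[lo:hi] <- res$cen; km_hat[lo:hi] <- res$km
    n_hat[lo:(hi + 1L)] <- res$n_hat
    cen_times[[i]] <- res$cen_t
    last_idx <- res$last
  }

  # optional adjustment so the event total matches the published count
  if (!is.null(curve$total_events)) {
    target <- curve$total_events
    lo <- lower[n_int]; hi <- upper[n_int]
    for (adj in 1:30) {
      if (sum(d) == target) break
      n_censor <- sum(cen[lo:hi]) + (sum(d) - target)
      n_censor <- min(nrisk[n_int], max(0L, n_censor))
      res <- run_interval(n_int, n_censor)
      if (all(d[lo:hi] == res$d) && all(cen[lo:hi] == res$cen)) break
      d[lo:hi] <- res$d; cen[lo:hi] <- res$cen; km_hat[lo:hi] <- res$km
      n_hat[lo:(hi + 1L)] <- res$n_hat
      cen_times[[n_int]] <- res$cen_t
    }
  }

  # assemble records: events at digitized times, censorings at their
  # allocated times, survivors censored administratively at the last time
  ev_times <- rep(t_s[d > 0], d[d > 0])
  cn_times <- unlist(cen_times)
  n_left <- n_hat[n_t + 1L]
  if (n_left > 0) cn_times <- c(cn_times, rep(t_s[n_t], n_left))
  ipd <- data.frame(
    time = c(ev_times, cn_times),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cn_times))))
  ipd <- ipd[ipd$time > 0, ]
  ipd <- ipd[order(ipd$time, -ipd$event), ]
  rownames(ipd) <- NULL
  km <- km_estimate(ipd)
  attr(ipd, "km_match") <- max(abs(eval_curve(km, t_s) - s))
  ipd
}

#' Kaplan-Meier product-limit estimate as a survival curve
#'
#' Thin wrapper around [survival::survfit()] returning the right-continuous
#' step function \eqn{\prod_{t_i \le t} (1 - d_i/n_i)} as a
#' [survival_curve()] (provenance `"kaplan-meier"`).
#'
#' @param ipd Data frame with columns `time` (months) and `event` (0/1).
#' @return A `survival_curve`; attributes `fit` (the `survfit` object) and
#'   `n` (number of records) are attached.
#' @export
km_estimate <- function(ipd) {
  ipd <- validate_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  out <- survival_curve(function(t) step(t), provenance = "kaplan-meier",
                        support_end = max(ipd$time))
  attr(out, "fit") <- fit
  attr(out, "n") <- nrow(ipd)
  out
}

#' Read / write digitized curves as delimited text
#'
#' `points` and `risk_table` live in two tab-separated files; the optional
#' event total is a header comment `# total_events: N` in the points file.
#' @param points_path,risk_path File paths.
#' @param curve A [digitized_curve()].
#' @return `read_digitized_curve` returns a `digitized_curve`.
#' @export
read_digitized_curve <- function(points_path, risk_path) {
  header <- readLines(points_path, n = 1)
  total <- NULL
  if (grepl("^#\\s*total_events:", header))
    total <- as.integer(sub("^#\\s*total_events:\\s*", "", header))
  pts <- utils::read.delim(points_path, comment.char = "#")
  rt <- utils::read.delim(risk_path)
  digitized_curve(pts, rt, total_events = total)
}

#' @rdname read_digitized_curve
#' @export
write_digitized_curve <- function(curve, points_path, risk_path) {
  stopifnot(inherits(curve, "digitized_curve"))
  con <- file(points_path, "w")
  on.exit(close(con))
  if (!is.null(curve$total_events))
    writeLines(sprintf("# total_events: %d", curve$total_events), con)
  utils::write.table(curve$points, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(curve$risk_table, risk_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(points_path)
}
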