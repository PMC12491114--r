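#' Pseudo individual patient data
#'
#' A `pseudo_ipd` is a minimal patient-level survival dataset: one row per
#' subject with a follow-up `time` (months) and an `event` indicator
#' (1 = event, 0 = censored). It is what the Kaplan-Meier reconstruction
#' produces and what the parametric fitting consumes.
#'
#' @param time Non-negative follow-up times in months.
#' @param event 0/1 event indicators.
#' @return A data frame of class `pseudo_ipd`.
#' @export
pseudo_ipd <- function(time, event) {
  time <- as.numeric(time); event <- as.integer(event)
  if (length(time) != length(event)) {
    stop("pseudo_ipd: time and event must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("pseudo_ipd: times must be finite and >= 0", call. = FALSE)
  }
  if (!all(event %in% c(0L, 1L))) {
    stop("pseudo_ipd: event must be 0 or 1", call. = FALSE)
  }
  structure(data.frame(time = time, event = event),
            class = c("pseudo_ipd", "data.frame"))
}

#' @rdname pseudo_ipd
#' @param x Data frame with columns `time`, `event`.
#' @export
as_pseudo_ipd <- function(x) {
  if (inherits(x, "pseudo_ipd")) return(x)
  if (!all(c("time", "event") %in% names(x))) {
    stop("as_pseudo_ipd: need columns 'time' and 'event'", call. = FALSE)
  }
  pseudo_ipd(x$time, x$event)
}

#' Digitized Kaplan-Meier curve with numbers at risk
#'
#' Container for coordinates read off a published survival figure (e.g. with
#' WebPlotDigitizer) together with the numbers-at-risk table printed beneath
#' it. Digitization noise can invert adjacent points, so survival values are
#' snapped to be non-increasing with a running minimum before use; a point at
#' `(0, 1)` is prepended if absent.
#'
#' @param points Data frame with columns `time`, `survival`.
#' @param risk_table Data frame with columns `time`, `n_at_risk` (at least two
#'   rows, non-increasing counts).
#' @param total_events Optional total event count, used to refine the
#'   final-interval allocation during reconstruction.
#' @return An object of class `digitized_km`.
#' @export
digitized_km <- function(points, risk_table, total_events = NULL) {
  stopifnot(all(c("time", "survival") %in% names(points)),
            all(c("time", "n_at_risk") %in% names(risk_table)))
  points <- points[order(points$time), c("time", "survival")]
  if (any(points$time < 0) || any(points$survival < 0 | points$survival > 1)) {
    stop("digitized_km: points must have time >= 0 and survival in [0, 1]",
         call. = FALSE)
  }
  if (points$time[1] > 0) {
    points <- rbind(data.frame(time = 0, survival = 1), points)
  }
  points$survival <- cummin(pmin(points$survival, 1))   # monotone snap
  risk_table <- risk_table[order(risk_table$time), c("time", "n_at_risk")]
  if (nrow(risk_table) < 2L) {
    stop("digitized_km: risk table needs at least two entries", call. = FALSE)
  }
  if (is.unsorted(-risk_table$n_at_risk)) {
    stop("digitized_km: n_at_risk must be non-increasing", call. = FALSE)
  }
  structure(list(points = points, risk_table = risk_table,
                 total_events = total_events),
            class = "digitized_km")
}

#' Reconstruct pseudo-IPD from a digitized Kaplan-Meier curve
#'
#' Implements the iterative reconstruction scheme of Guyot et al. (2012):
#' within each interval of the numbers-at-risk table, censoring times are
#' spread uniformly, event counts at each digitized drop are solved to match
#' the digitized survival, and the censoring count is adjusted until the
#' implied number at risk at the next risk-table time matches the printed one.
#' In the final interval (no closing risk-table entry) censoring is taken as
#' zero unless `total_events` was supplied, in which case it is adjusted so
#' the total event count matches; subjects still at risk after the last
#' digitized time are administratively censored there.
#'
#' @param km A [digitized_km].
#' @param max_iter Iteration cap per interval for the censoring adjustment.
#' @return A [pseudo_ipd] with exactly as many records as the initial number
#'   at risk.
#' @references Guyot P, Ades AE, Ouwens MJNM, Welton NJ (2012). Enhanced
#'   secondary analysis of survival data: reconstructing the data from
#'   published Kaplan-Meier survival curves. BMC Med Res Methodol 12:9.
#' @export
reconstruct_ipd <- function(km, max_iter = 50L) {
  stopifnot(inherits(km, "digitized_km"))
  pts <- km$points
  rt <- km$risk_table
  K <- nrow(pts)
  nint <- nrow(rt)
  ev_time <- numeric(0); cn_time <- numeric(0)

  KM_prev <- 1          # running product-limit estimate
  n_hat <- rt$n_at_risk[1]
  tot_events <- 0L

  for (i in seq_len(nint)) {
    t_lo <- rt$time[i]
    t_hi <- if (i < nint) rt$time[i + 1] else Inf
    # a digitized point at exactly the closing risk time reflects drops that
    # happened before that reading, so intervals are (t_lo, t_hi]
    ks <- which(pts$time > t_lo & pts$time <= t_hi)
    if (i == 1L) ks <- union(which(pts$time <= t_lo), ks)
    # survival level entering the next interval, for the initial censor guess
    k_next <- which(pts$time >= t_hi)
    S_hi <- if (length(k_next)) pts$survival[k_next[1]] else
      pts$survival[K]

    n_start <- n_hat
    if (i < nint) {
      # subjects expected at risk at t_hi absent censoring, minus the printed
      # number at risk, is the first guess at the interval's censoring count
      nc <- max(0L, round(n_start * S_hi / max(KM_prev, 1e-12)) -
                  rt$n_at_risk[i + 1])
    } else {
      nc <- 0L
    }

    sim <- NULL
    for (iter in seq_len(max_iter)) {
      sim <- .sim_interval(pts, ks, n_start, KM_prev, nc, t_lo,
                           if (is.finite(t_hi)) t_hi else max(pts$time))
      if (i < nint) {
        diff <- sim$n_end - rt$n_at_risk[i + 1]
        if (diff == 0L) break
        nc_new <- max(0L, nc + diff)
        if (nc_new == nc) break
        nc <- nc_new
      } else if (!is.null(km$total_events)) {
        diff <- (tot_events + sim$d_total) - km$total_events
        if (diff == 0L) break
        nc_new <- max(0L, nc + diff)
        if (nc_new == nc) break
        nc <- nc_new
      } else break
    }
    if (sim$n_end < 0) {
      stop(sprintf(
        "reconstruct_ipd: risk table inconsistent in interval starting at %g months",
        t_lo), call. = FALSE)
    }
    ev_time <- c(ev_time, sim$ev_time)
    cn_time <- c(cn_time, sim$cn_time)
    tot_events <- tot_events + sim$d_total
    KM_prev <- sim$KM_end
    n_hat <- sim$n_end
  }

  # subjects still at risk: administrative censoring at the end of follow-up
  if (n_hat > 0L) {
    t_end <- max(pts$time, rt$time)
    cn_time <- c(cn_time, rep(t_end, n_hat))
  }
  pseudo_ipd(c(ev_time, cn_time),
             c(rep(1L, length(ev_time)), rep(0L, length(cn_time))))
}

# walk the digitized points of one risk-table interval with nc censoring
# times spread uniformly over it; the event count at each digitized point
# solves the digitized drop given the running product-limit estimate.
# Censorings tied with an event time are processed after the events.
.sim_interval <- function(pts, ks, n_start, KM_prev, nc, t_lo, t_hi) {
  cens <- if (nc > 0L) t_lo + (seq_len(nc) - 0.5) / nc * (t_hi - t_lo)
          else numeric(0)
  n_hat <- n_start
  ev_time <- numeric(0)
  cn_used <- numeric(0)
  d_total <- 0L
  ci <- 1L
  drop_cens_upto <- function(tmax, strict) {
    while (ci <= length(cens) && n_hat > 0L &&
           (if (strict) cens[ci] < tmax else cens[ci] <= tmax)) {
      cn_used <<- c(cn_used, cens[ci])
      n_hat <<- n_hat - 1L
      ci <<- ci + 1L
    }
  }
  for (k in ks) {
    drop_cens_upto(pts$time[k], strict = TRUE)
    S_k <- pts$survival[k]
    if (KM_prev > 0 && n_hat > 0L) {
      d_k <- max(0L, min(n_hat, round(n_hat * (1 - S_k / KM_prev))))
      if (d_k > 0L) {
        KM_prev <- KM_prev * (1 - d_k / n_hat)
        ev_time <- c(ev_time, rep(pts$time[k], d_k))
        d_total <- d_total + d_k
        n_hat <- n_hat - d_k
      }
    }
  }
  drop_cens_upto(t_hi, strict = FALSE)
  list(ev_time = ev_time, cn_time = cn_used, d_total = d_total,
       KM_end = KM_prev, n_end = n_hat)
}

#' Product-limit (Kaplan-Meier) estimator
#'
#' Thin wrapper over [survival::survfit()] with the usual convention that
#' censorings tied with events are processed after the events. Serves as the
#' round-trip oracle for the reconstruction.
#'
#' @param ipd A [pseudo_ipd] (or data frame with `time`, `event`).
#' @return A data frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, describing the right-continuous step
#'   function (survival value applies from `time` onward).
#' @export
km_estimator <- function(ipd) {
  ipd <- as_pseudo_ipd(ipd)
  if (nrow(ipd) == 0L) stop("km_estimator: empty input", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, survival = sf$surv)
  structure(out, class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km A `km_curve` from [km_estimator()].
#' @param t Times in months.
#' @return Survival probabilities (right-continuous step function; 1 before
#'   the first event/censoring time).
#' @export
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$survival)[idx + 1L]
}

#' Read / write the plain-text formats of the reconstruction chain
#'
#' `read_digitized_km()` reads two CSV files (curve coordinates with columns
#' `time,survival`; risk table with columns `time,n_at_risk`);
#' `write_digitized_km()` writes them. `read_pseudo_ipd()` /
#' `write_pseudo_ipd()` use a single CSV with columns `time,event`.
#'
#' @param points_file,risk_file,file CSV paths.
#' @param km,ipd Objects to write.
#' @param total_events Optional total event count passed to [digitized_km()].
#' @return The read object, or (for writers) the input invisibly.
#' @export
read_digitized_km <- function(points_file, risk_file, total_events = NULL) {
  digitized_km(utils::read.csv(points_file), utils::read.csv(risk_file),
               total_events = total_events)
}

#' @rdname read_digitized_km
#' @export
write_digitized_km <- function(km, points_file, risk_file) {
  utils::write.csv(km$points, points_file, row.names = FALSE)
  utils::write.csv(km$risk_table, risk_file, row.names = FALSE)
  invisible(km)
}

#' @rdname read_digitized_km
#' @export
read_pseudo_ipd <- function(file) as_pseudo_ipd(utils::read.csv(file))

#' @rdname read_digitized_km
#' @export
write_pseudo_ipd <- function(ipd, file) {
  utils::write.csv(as_pseudo_ipd(ipd), file, row.names = FALSE)
  invisible(ipd)
}
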