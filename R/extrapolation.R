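#' National telemedicine session count from payer share
#'
#' Scales the count of sessions reimbursed by the Centers for Medicare &
#' Medicaid Services (CMS) up to a national total by dividing by CMS's
#' share of National Health Expenditures, the best available proxy for its
#' share of telemedicine volume. Defaults: 27,691,878 reimbursed sessions
#' (March 2020 - February 2021) at a 38% expenditure share, giving
#' 72,873,363 national sessions.
#'
#' @param cms_sessions CMS-reimbursed telemedicine session count.
#' @param cms_share CMS share of national health expenditures, in (0, 1].
#' @return National session count, rounded to the nearest integer.
#' @examples
#' estimate_total_sessions() # 72,873,363
#' @export
estimate_total_sessions <- function(cms_sessions = 27691878,
                                    cms_share = 0.38) {
  if (!is.numeric(cms_share) || cms_share <= 0 || cms_share > 1) {
    stop("`cms_share` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(cms_sessions) || cms_sessions <= 0) {
    stop("`cms_sessions` must be positive", call. = FALSE)
  }
  round(cms_sessions / cms_share)
}

#' Aggregate CO2 savings in metric tons
#'
#' Multiplies a per-session central net-savings estimate (grams) by a
#' session count and converts to metric tons (1e6 g). The raw value is
#' always computed; `rounding` selects the reporting convention
#' (`"hundred"` for national headline figures, `"ton"` for platform-level
#' figures, `"none"` for the raw value).
#'
#' @param per_session_net_g Central per-session net savings in grams
#'   (median by convention; mean optionally).
#' @param n_sessions Number of sessions.
#' @param rounding `"none"`, `"ton"`, or `"hundred"`.
#' @return Metric tons of CO2.
#' @examples
#' total_savings_tons(19812.45, 72873363, rounding = "hundred") # 1,443,800
#' @export
total_savings_tons <- function(per_session_net_g, n_sessions,
                               rounding = c("none", "ton", "hundred")) {
  rounding <- match.arg(rounding)
  if (any(per_session_net_g < 0) || any(n_sessions < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  tons <- per_session_net_g * n_sessions / 1e6
  switch(rounding,
    none = tons,
    ton = round(tons),
    hundred = round(tons / 100) * 100
  )
}

#' National and platform-level extrapolation report
#'
#' Combines [estimate_total_sessions()] and [total_savings_tons()] into
#' the headline accounting: national annual CO2 savings (rounded to the
#' nearest hundred tons, raw value alongside) and platform-level savings
#' for the observed session count.
#'
#' @param per_session_net_g Central per-session net savings in grams.
#' @param central `"median"` or `"mean"` — which central estimate
#'   `per_session_net_g` is; recorded in the report.
#' @param cms_sessions,cms_share See [estimate_total_sessions()].
#' @param platform_sessions Number of sessions observed on the platform
#'   after filtering (default 6,231,614).
#' @return A list of class `national_estimate` with fields
#'   `total_sessions`, `per_session_net_g`, `central_estimate_kind`,
#'   `total_savings_metric_tons_raw`, `total_savings_metric_tons_rounded`,
#'   `platform_sessions`, `platform_savings_metric_tons`.
#' @examples
#' national_estimate(19812.45)
#' @export
national_estimate <- function(per_session_net_g,
                              central = c("median", "mean"),
                              cms_sessions = 27691878,
                              cms_share = 0.38,
                              platform_sessions = 6231614) {
  central <- match.arg(central)
  total_sessions <- estimate_total_sessions(cms_sessions, cms_share)
  raw <- total_savings_tons(per_session_net_g, total_sessions)
  structure(
    list(
      total_sessions = total_sessions,
      per_session_net_g = per_session_net_g,
      central_estimate_kind = central,
      total_savings_metric_tons_raw = raw,
      total_savings_metric_tons_rounded = round(raw / 100) * 100,
      platform_sessions = platform_sessions,
      platform_savings_metric_tons =
        total_savings_tons(per_session_net_g, platform_sessions, "ton")
    ),
    class = "national_estimate"
  )
}

#' @export
print.national_estimate <- function(x, ...) {
  cat(sprintf("National telemedicine CO2 savings (%s-based)\n",
              x$central_estimate_kind))
  cat(sprintf("  sessions/year (national):   %s\n",
              format(x$total_sessions, big.mark = ",")))
  cat(sprintf("  per-session net savings:    %.2f g CO2\n",
              x$per_session_net_g))
  cat(sprintf("  national savings:           %s metric tons CO2/year\n",
              format(x$total_savings_metric_tons_rounded, big.mark = ",")))
  cat(sprintf("  platform savings (n=%s):  %s metric tons CO2\n",
              format(x$platform_sessions, big.mark = ","),
              format(x$platform_savings_metric_tons, big.mark = ",")))
  invisible(x)
}
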