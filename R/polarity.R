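## Immuno-gold filament-polarity statistics: summarise particle annotations
## and test for end-binding preference.

#' Summarise gold-particle annotations
#'
#' @param table Data frame with columns `image`, `particle`, `location`
#'   (one of off / on_body / on_end) and optionally `filament`.
#' @return List with `fraction_on_filament` (= (on_body + on_end)/total),
#'   `fraction_at_end` (= on_end / on-filament; NA when nothing is on a
#'   filament), `n_both_ends` (filaments carrying two or more end-bound
#'   particles, an upper bound on both-end binding since the annotations do
#'   not record which end; NA
#'   when no filament ids are available), and the raw counts.
#' @export
gold_summary <- function(table) {
  if (!nrow(table)) stop("empty annotation table")
  bad <- setdiff(unique(table$location), c("off", "on_body", "on_end"))
  if (length(bad)) stop("unknown location label(s): ", paste(bad, collapse = ", "))
  n <- nrow(table)
  n_end <- sum(table$location == "on_end")
  n_body <- sum(table$location == "on_body")
  on_fil <- n_end + n_body
  frac_end <- if (on_fil > 0) n_end / on_fil else NA_real_
  n_both <- NA_integer_
  if (!is.null(table$filament) && any(!is.na(table$filament))) {
    ends <- table[table$location == "on_end" & !is.na(table$filament), ]
    per_fil <- table(paste(ends$image, ends$filament))
    n_both <- sum(per_fil >= 2L)
  }
  list(fraction_on_filament = on_fil / n,
       fraction_at_end = frac_end,
       n_both_ends = n_both,
       counts = c(total = n, off = n - on_fil, on_body = n_body,
                  on_end = n_end))
}

#' Exact one-sided binomial test for end-binding preference
#'
#' Tests whether on-filament particles sit at an end more often than the
#' fraction `rho0` expected under uniform binding (which the caller must
#' supply, e.g. 2 * end-window length / filament length). Returns the exact
#' upper-tail probability `P[X >= n_end]` for
#' `X ~ Binomial(n_end + n_body, rho0)`.
#'
#' @param n_end,n_body Particle counts at ends and on bodies.
#' @param rho0 Expected end fraction under no preference, in (0, 1).
#' @return Exact one-sided p-value.
#' @examples
#' end_preference_test(8, 2, 0.2)
#' @export
end_preference_test <- function(n_end, n_body, rho0) {
  if (!is.finite(rho0) || rho0 <= 0 || rho0 >= 1)
    stop("`rho0` must lie strictly between 0 and 1")
  n_end <- as.integer(n_end); n_body <- as.integer(n_body)
  if (n_end < 0 || n_body < 0 || n_end + n_body < 1)
    stop("need n_end + n_body >= 1 with non-negative counts")
  stats::pbinom(n_end - 1L, n_end + n_body, rho0, lower.tail = FALSE)
}
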