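# Condition helpers. All package errors carry a class so callers can
# distinguish bad values (domain), missing reference coverage (coverage),
# unusable analysis input (degenerate) and malformed files (schema).

pm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pedmets_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pm_domain_error     <- function(msg, ...) pm_stop("pedmets_domain_error", msg, ...)
pm_coverage_error   <- function(msg, ...) pm_stop("pedmets_coverage_error", msg, ...)
pm_degenerate_error <- function(msg, ...) pm_stop("pedmets_degenerate_error", msg, ...)
pm_schema_error     <- function(msg, ...) pm_stop("pedmets_schema_error", msg, ...)
pm_config_error     <- function(msg, ...) pm_stop("pedmets_config_error", msg, ...)

# shared check: every present (non-NA) value strictly positive
check_positive <- function(x, field) {
  if (any(!is.na(x) & x <= 0))
    pm_domain_error("'%s' must be strictly positive", field)
  invisible(x)
}
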