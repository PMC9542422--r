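# Internal validation helpers shared across modules.

method_panels <- c("M1", "M2neg", "M2pos")
qc_types <- c("regular", "blank", "duplicate")
measurement_qualifiers <- c("detect", "estimate", "nondetect", "interference")
species_groups <- c("fish", "invertebrate", "plant", "other")
endpoint_subsets <- c("NoEffect", "LowEffect", "AcuteEffect")

# Assert that `df` carries the columns in `cols`; error names the missing ones.
check_columns <- function(df, cols, table_name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(
      sprintf(
        "schema error in `%s`: missing column%s %s",
        table_name, if (length(missing) > 1L) "s" else "",
        paste0("`", missing, "`", collapse = ", ")
      ),
      class = "tribscreen_schema_error"
    )
  }
  invisible(df)
}

check_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}

# Split a "M1;M2neg" panel string into a character vector of panels.
split_panels <- function(x) {
  out <- strsplit(x, "[;,[:space:]]+")
  lapply(out, function(p) {
    p <- p[nzchar(p)]
    bad <- setdiff(p, method_panels)
    if (length(bad) > 0L) {
      abort(sprintf("unknown method panel(s): %s", paste(bad, collapse = ", ")))
    }
    p
  })
}

# Regular (non-QC) samples drive all screening computations; blanks and
# duplicates only feed the QC reports.
regular_samples <- function(samples) {
  dplyr::filter(samples, .data$qc_type == "regular")
}

# Long (site_id, panel) coverage derived from the regular samples at a site.
site_panel_coverage <- function(samples) {
  reg <- regular_samples(samples)
  tibble(
    site_id = rep(reg$site_id, lengths(reg$panels)),
    panel = unlist(reg$panels, use.names = FALSE)
  ) |>
    distinct()
}

# Which sites monitor which chemicals: a chemical is monitored at a site when
# any regular sample there ran the chemical's panel.
monitored_sites <- function(samples, chemicals) {
  cov <- site_panel_coverage(samples)
  chemicals |>
    select("cas", "panel") |>
    inner_join(cov, by = "panel", relationship = "many-to-many") |>
    select("cas", "site_id")
}
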