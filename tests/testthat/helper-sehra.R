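# Shared fixtures and independent oracles.

# Smallest integer n whose implied CI half-width under the cluster design
# (deff and non-response divided back out) is within r*p -- an oracle for
# the sizing chain that never touches the closed form's ceiling.
brute_force_n <- function(p, z = 1.96, r = 0.2, deff = 2, nr = 0.2,
                          n_max = 200000L) {
  for (n in seq_len(n_max)) {
    half <- z * sqrt(deff * (1 + nr) * p * (1 - p) / n)
    if (half <= r * p + 1e-12) return(n)
  }
  stop("brute-force search exhausted")
}

make_frame <- function(enrollments, ids = NULL, ...) {
  ids <- ids %||% sprintf("S%02d", seq_along(enrollments))
  school_frame(data.frame(school_id = ids, enrollment = enrollments,
                          stringsAsFactors = FALSE, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_temp_csv <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, ...)
  path
}
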