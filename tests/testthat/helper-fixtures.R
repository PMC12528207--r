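# Write a small HMD-style Mx file and return its path.
# `rows` is a data.frame with columns year, age, female, male, total
# (character, already formatted).
write_mx_fixture <- function(rows, path = withr::local_tempfile(
                               fileext = ".txt",
                               .local_envir = parent.frame())) {
  writeLines(c(
    "Testland, Death rates (period 1x5)",
    "",
    sprintf("%-11s %-6s %-9s %-9s %-9s", "Year", "Age",
            "Female", "Male", "Total"),
    sprintf("%-11s %-6s %-9s %-9s %-9s",
            rows$year, rows$age, rows$female, rows$male, rows$total)
  ), path)
  path
}

basic_mx_rows <- function() {
  data.frame(
    year = "1751-1754",
    age = c("40", "41", "42"),
    female = ".", male = ".",
    total = c("0.01", "0.011", "0.012")
  )
}

# Exact rotation-model Gompertz fit table: ln_m0 = YA - A * alpha.
rotation_fits <- function(alphas = seq(0.06, 0.11, length.out = 10),
                          A = 100, YA = -0.6) {
  starts <- 1900 + 5 * (seq_along(alphas) - 1)
  tibble::tibble(
    population = "rot",
    period = period_label(starts, starts + 4),
    period_start = starts,
    period_end = starts + 4,
    alpha = alphas,
    ln_m0 = YA - A * alphas,
    r2 = 1
  )
}
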