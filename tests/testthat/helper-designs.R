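# small builders used across test files

std_model <- function(k = 5, rho = 0.5) parallel_items(k, rho = rho)

prepost_design <- function(n = 30, delta = 0.4, k = 5, c_alpha = 0.5, ...) {
  cron_design("prepost", n = n, delta = delta, k = k, c_alpha = c_alpha, ...)
}

bw_design <- function(n = 30, delta = 0.4, k = 5, c_alpha = 0.5, ...) {
  cron_design("betweenwithin", n = n, delta = delta, k = k,
              c_alpha = c_alpha, ...)
}

ts_design <- function(n = 50, delta = 0.7, k = 5, c_alpha = 0.5, ...) {
  cron_design("twosample", n = n, delta = delta, k = k, c_alpha = c_alpha, ...)
}

alpha_design <- function(n = 30, k = 5, c_alpha = 0.5, ...) {
  cron_design("alpha", n = n, k = k, c_alpha = c_alpha, ...)
}
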