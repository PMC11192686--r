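# package-level logging; silence with options(itasense.verbose = FALSE)
ita_log <- function(fmt, ...) {
  if (isTRUE(getOption("itasense.verbose", TRUE)))
    message("[itasense] ", sprintf(fmt, ...))
  invisible(NULL)
}

# Gamma((n)/2) / Gamma((n-1)/2) in log space, n may be large
gamma_ratio_half <- function(a, b) exp(lgamma(a) - lgamma(b))
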