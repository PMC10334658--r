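# ordered rank schema used throughout (kingdom -> genus)
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus")
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# canonical unordered-pair keys, used for edge joins across networks
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
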