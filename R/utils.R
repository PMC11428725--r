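# Resolve a column given either a bare name or a character scalar
# (possibly held in a variable), so the data-frame-first functions work
# both interactively and programmatically.
col_name <- function(quo) {
  val <- tryCatch(rlang::eval_tidy(quo), error = function(cnd) NULL)
  if (is.character(val) && length(val) == 1L) val else as_name(quo)
}
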