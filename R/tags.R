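#' Generate a run tag
#'
#' Run tags identify every data element a pipeline run produces. A tag is
#' seven uppercase letters (e.g. `"EBGNHJW"`), drawn uniformly from the
#' 26^7 tag space; collisions across runs follow the birthday bound.
#'
#' @param n Number of tags to draw.
#' @return Character vector of `n` tags matching `^[A-Z]{7}$`. Draws come
#'   from R's current random stream; call `set.seed()` first for
#'   reproducible tags.
#' @examples
#' set.seed(1)
#' make_tag()
#' @export
make_tag <- function(n = 1L) {
  vapply(seq_len(n), function(i)
    paste(sample(LETTERS, 7L, replace = TRUE), collapse = ""),
    character(1))
}
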