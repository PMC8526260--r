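#' Standard 12-lead names, in conventional order
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

#' Beat class labels in reporting order
#'
#' Eight myocardial-infarction localizations — anterior (A), anteroseptal
#' (AS), anterolateral (AL), inferior (I), inferolateral (IL),
#' inferoposterior (IP), inferoposterolateral (IPL), posterior (P) — plus
#' healthy controls (H) and other diseases (O).
#' @export
MI_CLASSES <- c("A", "AS", "AL", "I", "IL", "IP", "IPL", "P", "H", "O")

# Set a temporary RNG state, restoring the caller's on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
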