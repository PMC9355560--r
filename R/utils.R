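#' Derive a reproducible stage seed from a master seed
#'
#' Hashes a stage label into a 32-bit-safe integer seed so that one master
#' seed deterministically yields distinct, stable seeds for every pipeline
#' stage and subject.
#'
#' @param master integer master seed.
#' @param label character scalar naming the stage (e.g. `"dms/subj03"`).
#' @return An integer seed in `[1, 2147483562]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483562
  as.integer((abs(master) %% 1048576 * 2039 + h) %% 2147483562 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("instrudecode_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
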