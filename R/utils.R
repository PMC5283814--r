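# Shared helpers: well naming, parameter vocabulary, seed handling.

# Screen parameter names, in canonical order. `cellNumber` is the total count;
# the remaining five are percent-of-total phase occupancies.
SCREEN_PARAMS <- c("cellNumber", "subG1", "G1", "S", "G2M", "overG2")
PHASES <- c("subG1", "G1", "S", "G2M", "overG2")
WELL_ROLES <- c("sample", "neg_ctrl", "gfp_ctrl", "mock", "pos_ctrl")
# The screen's negative-control pool: non-targeting siRNA plus GFP siRNA.
NEGATIVE_ROLES <- c("neg_ctrl", "gfp_ctrl")

#' Well names of a multiwell plate
#'
#' Row-major well labels (`A01`, `A02`, ..., `H12`) for a standard plate.
#'
#' @param nrow,ncol Plate dimensions; defaults give the 96-well format.
#' @return Character vector of length `nrow * ncol`.
#' @export
#' @examples
#' head(well_names())
well_names <- function(nrow = 8, ncol = 12) {
  rows <- LETTERS[seq_len(nrow)]
  as.vector(t(outer(rows, sprintf("%02d", seq_len(ncol)), paste0)))
}

well_regex <- function(nrow = 8, ncol = 12) {
  sprintf("^[A-%s](0[1-9]|1[0-%d])$", LETTERS[nrow], ncol - 10)
}

is_valid_well <- function(x, nrow = 8, ncol = 12) {
  grepl(well_regex(nrow, ncol), x)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a base seed, staying within
# 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  # double arithmetic: 7919 * 2^31 exceeds integer range but not 2^53
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647)
}

require_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
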