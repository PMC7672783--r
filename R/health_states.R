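#' Enumerate the model's health states
#'
#' The disease course of relapsing-remitting multiple sclerosis (RRMS) is
#' represented by 20 health states defined on the Expanded Disability Status
#' Scale (EDSS): 10 RRMS states (EDSS 0--9), 9 secondary progressive (SPMS)
#' states (EDSS 1--9), and death. State order is fixed package-wide: RRMS
#' EDSS 0..9 occupy indices 1..10, SPMS EDSS 1..9 indices 11..19, and DEAD
#' index 20.
#'
#' @return A data frame with columns `index`, `course` (factor with levels
#'   `RRMS`, `SPMS`, `DEAD`), `edss` (integer, `NA` for death) and `label`.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  df <- data.frame(
    index = seq_len(20L),
    course = factor(
      c(rep("RRMS", 10L), rep("SPMS", 9L), "DEAD"),
      levels = c("RRMS", "SPMS", "DEAD")
    ),
    edss = c(0:9, 1:9, NA_integer_)
  )
  df$label <- ifelse(
    df$course == "DEAD", "DEAD",
    paste0(df$course, "_EDSS", df$edss)
  )
  df
}

# fixed indices used throughout the engine
.STATE_DEAD <- 20L
.N_STATES <- 20L
.RRMS_IDX <- 1:10
.SPMS_IDX <- 11:19

#' Index of a health state in the package-wide state order
#'
#' @param course `"RRMS"`, `"SPMS"` or `"DEAD"`.
#' @param edss Integer EDSS level (ignored for `"DEAD"`).
#' @return Integer state index in 1..20.
#' @export
state_index <- function(course, edss = NA) {
  course <- match.arg(course, c("RRMS", "SPMS", "DEAD"))
  if (course == "DEAD") return(.STATE_DEAD)
  edss <- as.integer(edss)
  if (course == "RRMS") {
    if (is.na(edss) || edss < 0L || edss > 9L) {
      stop("RRMS EDSS must be an integer in 0..9")
    }
    return(1L + edss)
  }
  if (is.na(edss) || edss < 1L || edss > 9L) {
    stop("SPMS EDSS must be an integer in 1..9")
  }
  10L + edss
}

# EDSS level per state index (NA for DEAD); used for mortality multipliers,
# forced treatment stop, utilities and costs
state_edss <- function() c(0:9, 1:9, NA_integer_)

# logical vector: alive states
alive_states <- function() seq_len(.N_STATES) != .STATE_DEAD
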