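.LEVEL_NAMES <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5))

#' Vertebral index naming
#'
#' Vertebral levels use the numeric scheme 1 = C1 ... 7 = C7, 8 = T1 ...
#' 19 = T12, 20 = L1 ... 24 = L5. \code{levelName} converts indices to names,
#' \code{levelIndex} parses names (or passes numeric indices through), and
#' \code{diskPairName} names the disk below a vertebra ("C2-C3" for index 2).
#'
#' @param index integer vertebral index (1-24).
#' @param name character like "C4", "T10", "L2", or a numeric index.
#' @return \code{levelName}/\code{diskPairName}: character;
#'   \code{levelIndex}: integer.
#' @examples
#' levelName(8)        # "T1"
#' levelIndex("L1")    # 20
#' diskPairName(2)     # "C2-C3"
#' @export
levelName <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L) || any(index > 24L))
    stop("vertebral index must lie in 1..24")
  .LEVEL_NAMES[index]
}

#' @rdname levelName
#' @export
levelIndex <- function(name) {
  if (is.numeric(name)) {
    idx <- as.integer(name)
  } else {
    idx <- match(toupper(trimws(name)), .LEVEL_NAMES)
  }
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > 24L))
    stop("unrecognised vertebral level: ",
         paste(name[is.na(idx) | idx < 1L | idx > 24L], collapse = ", "))
  idx
}

#' @rdname levelName
#' @export
diskPairName <- function(index) {
  paste0(levelName(index), "-", levelName(as.integer(index) + 1L))
}
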