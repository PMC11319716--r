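## Inheritance-mode codings.
##
## A genotype is the minor-allele count g in {0,1,2}. "Original" direction
## codes the minor allele; "reverse" applies the same mode to the major
## allele, i.e. to 2 - g. The six (mode, direction) maps over g = (0,1,2):
##   additive/original  (0,1,2)    additive/reverse  (2,1,0)
##   dominant/original  (0,1,1)    dominant/reverse  (1,1,0)
##   recessive/original (0,0,1)    recessive/reverse (1,0,0)
## so that dominant/reverse == 1 - recessive/original and
## recessive/reverse == 1 - dominant/original.

.COD_MAPS <- list(
  Add  = c(0, 1, 2), AddR = c(2, 1, 0),
  Dom  = c(0, 1, 1), DomR = c(1, 1, 0),
  Rec  = c(0, 0, 1), RecR = c(1, 0, 0))

.COD_MODE <- c(Add = "additive", AddR = "additive",
               Dom = "dominant", DomR = "dominant",
               Rec = "recessive", RecR = "recessive")
.COD_DIR <- c(Add = "original", AddR = "reverse",
              Dom = "original", DomR = "reverse",
              Rec = "original", RecR = "reverse")

.codingKey <- function(mode, direction) {
  mode <- match.arg(mode, c("additive", "dominant", "recessive"))
  direction <- match.arg(direction, c("original", "reverse"))
  key <- c(additive = "Add", dominant = "Dom", recessive = "Rec")[[mode]]
  if (direction == "reverse") key <- paste0(key, "R")
  key
}

#' Apply an inheritance-mode coding to genotypes
#'
#' Maps minor-allele counts to the model covariate for one of the six
#' (mode, direction) codings. `reverse` applies the mode to the major allele,
#' i.e. to `2 - g`.
#'
#' @param g integer vector of genotypes in `{0, 1, 2}` (NA allowed).
#' @param mode one of `"additive"`, `"dominant"`, `"recessive"`.
#' @param direction one of `"original"`, `"reverse"`.
#' @return numeric vector of coded values.
#' @examples
#' applyCoding(0:2, "dominant")               # 0 1 1
#' applyCoding(0:2, "recessive", "reverse")   # 1 0 0
#' @export
applyCoding <- function(g, mode = c("additive", "dominant", "recessive"),
                        direction = c("original", "reverse")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g)))
    stop("invalid genotype: entries must be 0, 1 or 2")
  .COD_MAPS[[.codingKey(mode, direction)]][as.integer(g) + 1L]
}

## internal fast path: coding by key ("Add", "DomR", ...)
.codeByKey <- function(g, key) .COD_MAPS[[key]][g + 1L]

#' The six inheritance-mode codings
#'
#' @return data.frame with one row per coding: short key, mode, direction and
#'   the coded values for genotypes 0, 1, 2.
#' @export
codingTable <- function() {
  keys <- names(.COD_MAPS)
  data.frame(coding = keys,
             mode = unname(.COD_MODE[keys]),
             direction = unname(.COD_DIR[keys]),
             g0 = vapply(.COD_MAPS, `[`, 0, 1),
             g1 = vapply(.COD_MAPS, `[`, 0, 2),
             g2 = vapply(.COD_MAPS, `[`, 0, 3),
             row.names = NULL)
}
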