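# Pedigree handling and the numerator relationship matrix A.
#
# A is built with Henderson's tabular method and inverted directly with the
# Henderson/Quaas rules that account for inbreeding; both are O(n^2) on the
# sorted pedigree and are validated against each other in the test suite.

#' Construct and validate a pedigree
#'
#' Records are `(animal, sire, dam)` with unknown parents coded `NA`, `"0"`
#' or `""`.  Parents that appear only in the sire/dam columns are added as
#' founder records.  The pedigree is topologically sorted so parents precede
#' offspring; cycles (an animal its own ancestor), duplicate animals and ids
#' used as both sire and dam are rejected.  Inbreeding coefficients `F` are
#' computed from the diagonal of the tabular relationship matrix.
#'
#' @param df data.frame with character columns `animal`, `sire`, `dam`.
#' @return a `pedigree`: data.frame `(animal, sire, dam, f)` in
#'   parents-first order.
#' @export
pedigree <- function(df) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) abort("pedigree needs columns animal, sire, dam")
  ped <- data.frame(lapply(df[need], as.character), stringsAsFactors = FALSE)
  unk <- function(v) ifelse(is.na(v) | v == "0" | v == "", NA_character_, v)
  ped$sire <- unk(ped$sire); ped$dam <- unk(ped$dam)
  if (anyDuplicated(ped$animal)) {
    abort("duplicate animal id(s): ",
          paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  }
  both <- intersect(stats::na.omit(ped$sire), stats::na.omit(ped$dam))
  if (length(both)) {
    abort("id(s) used as both sire and dam: ", paste(both, collapse = ", "))
  }
  implicit <- setdiff(c(ped$sire, ped$dam), c(ped$animal, NA))
  if (length(implicit)) {
    ped <- rbind(data.frame(animal = implicit, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
  }
  # Kahn topological sort on parent -> offspring edges
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) children[[p]] <- c(children[[p]], i)
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) != n) {
    abort("pedigree contains a cycle involving: ",
          paste(ped$animal[setdiff(seq_len(n), order_out)], collapse = ", "))
  }
  ped <- ped[order_out, , drop = FALSE]
  rownames(ped) <- NULL
  out <- structure(ped, class = c("pedigree", "data.frame"))
  out$f <- diag(a_matrix(out)) - 1
  out
}

#' @rdname pedigree
#' @param path CSV file with columns `animal,sire,dam` (unknown parent `0`
#'   or empty).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  names(df) <- tolower(names(df))
  pedigree(df)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d animals (%d founders), mean F = %.4f\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam)), mean(x$f)))
  invisible(x)
}

# internal: parent indices on the sorted pedigree, 0 = unknown
.parent_index <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  list(sire = ifelse(is.na(ped$sire), 0L, idx[ped$sire]),
       dam  = ifelse(is.na(ped$dam), 0L, idx[ped$dam]))
}

#' Numerator relationship matrix (Henderson tabular method)
#'
#' Builds the additive relationship matrix A on the sorted pedigree:
#' \eqn{a_{ii} = 1 + \tfrac12 a_{s(i),d(i)}} and, for earlier animals j,
#' \eqn{a_{ij} = \tfrac12 (a_{j,s(i)} + a_{j,d(i)})}, with unknown parents
#' contributing 0.  The diagonal is `1 + F` with `F` the inbreeding
#' coefficient.
#'
#' @param ped a [pedigree()].
#' @return symmetric matrix with animal ids as dimnames.
#' @export
a_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  p <- .parent_index(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- p$sire[i]; d <- p$dam[i]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[i, j] <- v
      A[j, i] <- v
    }
  }
  A
}

#' Direct inverse of the numerator relationship matrix
#'
#' Henderson's rules with the Quaas inbreeding adjustment: each animal
#' contributes \eqn{\alpha_i = 1 / d_i} to the inverse, where the Mendelian
#' sampling variance is \eqn{d_i = 0.5 - 0.25 (F_s + F_d)} with both
#' parents known, \eqn{0.75 - 0.25 F_p} with one, and 1 with none.  Never
#' forms or factorizes A itself.
#'
#' @param ped a [pedigree()].
#' @return the inverse relationship matrix with animal ids as dimnames.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  p <- .parent_index(ped)
  f <- ped$f
  Ai <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- p$sire[i]; d <- p$dam[i]
    di <- if (s > 0L && d > 0L) {
      0.5 - 0.25 * (f[s] + f[d])
    } else if (s > 0L) {
      0.75 - 0.25 * f[s]
    } else if (d > 0L) {
      0.75 - 0.25 * f[d]
    } else 1
    al <- 1 / di
    Ai[i, i] <- Ai[i, i] + al
    for (q in c(s, d)) {
      if (q > 0L) {
        Ai[i, q] <- Ai[i, q] - al / 2
        Ai[q, i] <- Ai[q, i] - al / 2
      }
    }
    if (s > 0L) Ai[s, s] <- Ai[s, s] + al / 4
    if (d > 0L) Ai[d, d] <- Ai[d, d] + al / 4
    if (s > 0L && d > 0L) {
      Ai[s, d] <- Ai[s, d] + al / 4
      Ai[d, s] <- Ai[d, s] + al / 4
    }
  }
  Ai
}
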