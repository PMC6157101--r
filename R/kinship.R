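## Theoretical kinship from pedigrees and the error-covariance structure.

## Topological order of a pedigree (parents before offspring).  Errors with
## a cycle path if the pedigree graph is cyclic.
pedigreeOrder <- function(ped) {
  id <- ped@id
  n <- length(id)
  idx <- stats::setNames(seq_len(n), id)
  fa <- idx[ped@father]; mo <- idx[ped@mother]  # NA for unknown
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) if (!is.na(p)) {
      indeg[i] <- indeg[i] + 1L
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    # walk parent links among the leftover individuals to exhibit a cycle
    path <- left[1]
    repeat {
      i <- path[length(path)]
      nxt <- c(fa[i], mo[i])
      nxt <- nxt[!is.na(nxt) & nxt %in% left][1]
      if (nxt %in% path) {
        cyc <- c(path[which(path == nxt):length(path)], nxt)
        stop("pedigree contains a cycle: ",
             paste(id[cyc], collapse = " -> "))
      }
      path <- c(path, nxt)
    }
  }
  ord
}

#' Theoretical kinship coefficients from a pedigree
#'
#' Computes the kinship coefficient matrix Phi by the standard recursion:
#' founders are unrelated and non-inbred (`phi_ii = 1/2`), and for an
#' individual i with parents f and m, `phi_ii = (1 + phi_fm) / 2` and
#' `phi_ij = (phi_fj + phi_mj) / 2` for any j that is not a descendant of i
#' (unknown parents contribute 0).  Inbreeding is handled by the recursion
#' itself.  The result is independent of the record order in the input.
#'
#' @param ped a [Pedigree-class] object.
#' @return Symmetric matrix of kinship coefficients with ids as dimnames,
#'   rows in the input's individual order.
#' @examples
#' trio <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"))
#' kinshipCoefficients(trio)["f", "c"]  # 0.25
#' @export
kinshipCoefficients <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  idx <- stats::setNames(seq_len(n), ped@id)
  fa <- idx[ped@father]; mo <- idx[ped@mother]
  ord <- pedigreeOrder(ped)
  phi <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  done <- integer(0)
  for (i in ord) {
    f <- fa[i]; m <- mo[i]
    pf <- function(j, p) if (is.na(p)) 0 else phi[p, j]
    for (j in done) {
      v <- 0.5 * (pf(j, f) + pf(j, m))
      phi[i, j] <- phi[j, i] <- v
    }
    phi[i, i] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) phi[f, m] else 0)
    done <- c(done, i)
  }
  phi
}

#' Error-covariance structure from kinship coefficients
#'
#' The residual errors of the mixed model have covariance
#' `sigma2 * K`.  In `relationship` scaling (the default) `K = 2 Phi`, the
#' expected additive relationship matrix, which has unit diagonal for
#' non-inbred subjects so that `sigma2` is the residual variance of an
#' outbred singleton.  `kinship` scaling returns Phi unchanged.
#'
#' @param phi symmetric kinship coefficient matrix (e.g. from
#'   [kinshipCoefficients()]), or an identity-structured matrix for
#'   unrelated samples.
#' @param scaleMode `"relationship"` (2 Phi) or `"kinship"` (Phi).
#' @param tol positive-definiteness tolerance.
#' @return A [KinshipMatrix-class] holding the validated PD matrix.
#' @export
errorCovariance <- function(phi, scaleMode = c("relationship", "kinship"),
                            tol = 1e-10) {
  scaleMode <- match.arg(scaleMode)
  phi <- as.matrix(phi)
  if (max(abs(phi - t(phi))) > 1e-8) stop("kinship matrix must be symmetric")
  K <- if (scaleMode == "relationship") 2 * phi else phi
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol)
    stop(sprintf(paste0("error-covariance matrix is not positive definite ",
                        "(smallest eigenvalue %.3g); consider a jitter or ",
                        "check the pedigree"), min(ev)))
  kinshipMatrix(K, rownames(phi))
}

#' Read a PED/FAM-style pedigree file
#'
#' Whitespace- or tab-delimited, no header, columns: family id, individual
#' id, father id, mother id, optional sex, optional phenotype.  `0` denotes
#' an unknown parent.
#'
#' @param path file path.
#' @return A [Pedigree-class] object.
#' @export
readPedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 4)
    stop("pedigree file needs at least 4 columns: fam, id, father, mother")
  sex <- if (ncol(tab) >= 5) suppressWarnings(as.integer(tab[[5]]))
         else NA_integer_
  pedigree(id = tab[[2]], father = tab[[3]], mother = tab[[4]],
           sex = sex, famId = tab[[1]])
}

#' Write a pedigree in PED/FAM style
#'
#' @param ped a [Pedigree-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  tab <- data.frame(
    fam = ifelse(is.na(ped@famId), "0", ped@famId),
    id = ped@id,
    father = ifelse(is.na(ped@father), "0", ped@father),
    mother = ifelse(is.na(ped@mother), "0", ped@mother),
    sex = ifelse(is.na(ped@sex), 0L, ped@sex))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a kinship matrix from TSV
#'
#' Expects a header row of subject ids and a leading column of subject ids.
#'
#' @param path file path.
#' @return A [KinshipMatrix-class] object.
#' @export
readKinship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  kinshipMatrix(as.matrix(tab), rownames(tab))
}

#' Write a kinship matrix to TSV
#'
#' @param kin a [KinshipMatrix-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeKinship <- function(kin, path) {
  m <- kin@values
  out <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
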