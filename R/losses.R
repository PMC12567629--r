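# Distillation losses. All reductions are means over the batch, so values
# are invariant to batch size.

log_softmax <- function(l) {
  m <- apply(l, 1, max)
  z <- l - m
  z - log(rowSums(exp(z)))
}

softmax_rows <- function(l) exp(log_softmax(l))

check_logits <- function(l, name = "logits") {
  if (!is.matrix(l)) stop(name, " must be a B x K matrix", call. = FALSE)
  l
}

#' Cross-entropy loss on hard labels
#'
#' Mean over the batch of the negative log softmax probability of the true
#' class.
#'
#' @param logits `B x K` matrix of student logits.
#' @param labels integer vector of 0-based class codes in `[0, K)`.
#' @return scalar loss.
#' @export
ce_loss <- function(logits, labels) {
  check_logits(logits)
  labels <- as.integer(labels)
  K <- ncol(logits)
  if (any(labels < 0 | labels >= K))
    stop("labels must lie in [0, ", K, ")", call. = FALSE)
  ls <- log_softmax(logits)
  -mean(ls[cbind(seq_len(nrow(logits)), labels + 1L)])
}

#' Temperature-scaled distillation loss
#'
#' `tau^2 * KL(softmax(l_T / tau) || softmax(l_S / tau))`, mean over the
#' batch, with the teacher's softened distribution as the reference. The
#' `tau^2` factor keeps soft-target gradient magnitudes comparable across
#' temperatures.
#'
#' @param teacher_logits,student_logits `B x K` matrices of equal shape.
#' @param tau temperature (> 0).
#' @return scalar loss (>= 0; exactly 0 when the logit matrices coincide).
#' @export
kd_loss <- function(teacher_logits, student_logits, tau = 4) {
  check_logits(teacher_logits, "teacher_logits")
  check_logits(student_logits, "student_logits")
  if (!all(dim(teacher_logits) == dim(student_logits)))
    stop("teacher and student logits differ in shape", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  lt <- log_softmax(teacher_logits / tau)
  ls <- log_softmax(student_logits / tau)
  kl <- rowSums(exp(lt) * (lt - ls))
  tau^2 * mean(kl)
}

#' Single-teacher distillation objective
#'
#' `(1 - lambda) * L_CE + lambda * L_KD`: the convex combination of the
#' hard-label cross entropy and the temperature-scaled distillation term.
#'
#' @param student_logits `B x K` student logits.
#' @param labels 0-based hard labels.
#' @param teacher_logits `B x K` teacher logits.
#' @param lambda balance in `[0, 1]`.
#' @param tau temperature.
#' @return scalar loss.
#' @export
vanilla_kd_objective <- function(student_logits, labels, teacher_logits,
                                 lambda, tau = 4) {
  if (lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  (1 - lambda) * ce_loss(student_logits, labels) +
    lambda * kd_loss(teacher_logits, student_logits, tau)
}

#' Two-teacher distillation objective
#'
#' `(1 - lambda) * L_CE + lambda * ((1 - alpha) * L_KD^T1 + alpha * L_KD^T2)`
#' where teacher 1 sees the raw series and teacher 2 the image
#' representation of the same window. `alpha = 0` or `1` reduces to the
#' single-teacher objective; `alpha = 0.5` weighs both teachers equally
#' (the averaging configuration).
#'
#' @param student_logits `B x K` student logits.
#' @param labels 0-based hard labels.
#' @param teacher1_logits,teacher2_logits `B x K` teacher logits.
#' @param lambda,alpha weights in `[0, 1]`.
#' @param tau temperature.
#' @return scalar loss.
#' @export
multi_teacher_objective <- function(student_logits, labels, teacher1_logits,
                                    teacher2_logits, lambda, alpha, tau = 4) {
  if (lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  if (alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  (1 - lambda) * ce_loss(student_logits, labels) +
    lambda * ((1 - alpha) * kd_loss(teacher1_logits, student_logits, tau) +
                alpha * kd_loss(teacher2_logits, student_logits, tau))
}

#' Gradient of the distillation objective w.r.t. student logits
#'
#' Analytic gradient of [multi_teacher_objective()] (or, with a single or
#' no teacher, of its reductions) in the student's logits; this is what
#' the SGD engine consumes each step. Matches finite differences to first
#' order.
#'
#' @param student_logits `B x K` student logits.
#' @param labels 0-based hard labels.
#' @param teacher1_logits,teacher2_logits optional `B x K` teacher logits.
#' @param lambda,alpha,tau objective weights and temperature.
#' @return `B x K` gradient matrix.
#' @export
distill_logit_grad <- function(student_logits, labels,
                               teacher1_logits = NULL,
                               teacher2_logits = NULL,
                               lambda = 0, alpha = 0, tau = 4) {
  B <- nrow(student_logits); K <- ncol(student_logits)
  p <- softmax_rows(student_logits)
  y <- matrix(0, B, K)
  y[cbind(seq_len(B), as.integer(labels) + 1L)] <- 1
  g <- (1 - lambda) * (p - y) / B
  if (lambda > 0) {
    s <- softmax_rows(student_logits / tau)
    add_t <- function(tl, w) {
      t <- softmax_rows(tl / tau)
      w * tau * (s - t) / B
    }
    if (!is.null(teacher1_logits) && !is.null(teacher2_logits)) {
      g <- g + add_t(teacher1_logits, lambda * (1 - alpha)) +
        add_t(teacher2_logits, lambda * alpha)
    } else if (!is.null(teacher1_logits)) {
      g <- g + add_t(teacher1_logits, lambda)
    } else if (!is.null(teacher2_logits)) {
      g <- g + add_t(teacher2_logits, lambda)
    }
  }
  g
}
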