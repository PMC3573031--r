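# Independent reference implementations used as oracles.

# forward/backward partial-F stepwise regression via stats::lm with
# add1/drop1 F-tests (independent of the package's linear algebra)
stepwise_oracle <- function(x, y, p_enter = 0.10, p_remove = 0.15,
                            max_iter = 60L) {
  df <- data.frame(y = y, x)
  vars <- colnames(x)
  sel <- character(0)
  iter <- 0L
  repeat {
    if (iter >= max_iter) break
    excl <- setdiff(vars, sel)
    if (length(excl) == 0L) break
    fit <- lm(reformulate(c("1", sel), "y"), data = df)
    ad <- add1(fit, scope = reformulate(c(sel, excl)), test = "F")
    pv <- ad[["Pr(>F)"]][-1]
    j <- which.min(pv)
    if (pv[j] >= p_enter) break
    sel <- c(sel, excl[j])
    iter <- iter + 1L
    repeat {
      fit <- lm(reformulate(sel, "y"), data = df)
      dr <- drop1(fit, test = "F")
      pd <- dr[["Pr(>F)"]][-1]
      worst <- which.max(pd)
      if (length(sel) > 1L && pd[worst] > p_remove) sel <- sel[-worst]
      else break
    }
  }
  if (length(sel) == 0L) return(NULL)
  fit <- lm(reformulate(sel, "y"), data = df)
  list(selected = match(sel, vars),
       weights = unname(coef(fit)[-1]))
}

# mutual information by explicit enumeration of all 25 x 25
# target/selection pairs from a 9 x 9 offset distribution
mi_bruteforce <- function(off) {
  joint <- matrix(0, 25, 25)
  for (tr in 1:5) for (tc in 1:5) {
    ti <- (tr - 1) * 5 + tc
    cond <- matrix(0, 5, 5)
    for (sr in 1:5) for (sc in 1:5)
      cond[sr, sc] <- off[sr - tr + 5, sc - tc + 5]
    cond <- cond / sum(cond)
    for (sr in 1:5) for (sc in 1:5)
      joint[ti, (sr - 1) * 5 + sc] <- cond[sr, sc] / 25
  }
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in 1:25) for (j in 1:25)
    if (joint[i, j] > 0)
      s <- s + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  s
}
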