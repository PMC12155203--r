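#' Kaplan-Meier survival estimate with Greenwood log-log 95% CI
#'
#' Product-limit estimator per group, computed with the survival package
#' (\code{conf.type = "log-log"}).
#'
#' @param data \code{data.frame} with columns \code{time} (days),
#'   \code{event} (1 = death, 0 = censored) and optionally \code{group}.
#' @param group Restrict to one group label; default uses all rows, split by
#'   group when present.
#' @return \code{data.frame}: \code{group}, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{surv}, \code{lower}, \code{upper}.
#' @export
kmEstimate <- function(data, group = NULL) {
    if (!is.null(group)) data <- data[data$group %in% group, , drop = FALSE]
    if (!nrow(data)) stop("no observations", if (!is.null(group))
        paste0(" in group '", group, "'"))
    if (is.null(data$group)) data$group <- "all"
    out <- lapply(split(data, data$group), function(d) {
        fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                                 conf.type = "log-log")
        data.frame(group = d$group[1], time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, surv = fit$surv,
                   lower = ifelse(is.na(fit$lower) & fit$surv == 1, 1,
                                  fit$lower),
                   upper = ifelse(is.na(fit$upper) & fit$surv == 1, 1,
                                  fit$upper),
                   row.names = NULL)
    })
    do.call(rbind, c(out, make.row.names = FALSE))
}

#' Log-rank comparison of two survival distributions
#'
#' Standard 1-df log-rank test (hypergeometric variance, no extra ties
#' correction), via \code{\link[survival]{survdiff}}.
#'
#' @param data As in \code{\link{kmEstimate}}, with a \code{group} column.
#' @param groupA,groupB The two group labels to compare.
#' @return List: \code{chisq}, \code{df}, \code{p}.
#' @export
logrankTest <- function(data, groupA, groupB) {
    d <- data[data$group %in% c(groupA, groupB), , drop = FALSE]
    if (!all(c(groupA, groupB) %in% d$group))
        stop("both groups must be nonempty")
    if (sum(d$event) == 0L) stop("no events: log-rank test undefined")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    chisq <- unname(sd$chisq)
    list(chisq = chisq, df = 1L,
         p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Welch t-test on per-plate survival proportions
#'
#' Two-sample unpaired two-tailed t-test on plate-level survival fractions
#' (heat-shock scoring convention: each plate contributes one proportion).
#' When every plate proportion is identical across both groups, p = 1 by
#' convention; when both groups are internally constant but differ, p = 0.
#'
#' @param reps \code{data.frame} with columns \code{group}, \code{n_scored},
#'   \code{n_alive} (one row per plate).
#' @param groupA,groupB Labels to compare.
#' @return List: \code{t}, \code{p}, \code{summary} (per-group mean and SD of
#'   the survival proportion).
#' @export
proportionTtest <- function(reps, groupA, groupB) {
    stopifnot(all(reps$n_alive >= 0), all(reps$n_alive <= reps$n_scored))
    pa <- reps$n_alive[reps$group == groupA] /
          reps$n_scored[reps$group == groupA]
    pb <- reps$n_alive[reps$group == groupB] /
          reps$n_scored[reps$group == groupB]
    if (length(pa) < 2L || length(pb) < 2L)
        stop("need at least 2 plates per group")
    summ <- data.frame(group = c(groupA, groupB),
                       mean = c(mean(pa), mean(pb)),
                       sd = c(stats::sd(pa), stats::sd(pb)))
    if (stats::sd(pa) == 0 && stats::sd(pb) == 0) {
        eq <- mean(pa) == mean(pb)
        return(list(t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                    summary = summ))
    }
    tt <- stats::t.test(pb, pa, var.equal = FALSE)
    list(t = unname(tt$statistic), p = tt$p.value, summary = summ)
}

#' Convert plate-level daily survival counts to pseudo-individual records
#'
#' The starvation assays score plates daily; for Kaplan-Meier input each
#' death observed on a day becomes an event at that day and worms still alive
#' at a plate's last scored day are censored there.
#'
#' @param plates \code{data.frame} with columns \code{day}, \code{group},
#'   \code{n_alive}, \code{n_dead} (\code{n_dead} = newly observed deaths on
#'   that day).
#' @return \code{data.frame} with \code{time}, \code{event}, \code{group}.
#' @export
platesToSurvival <- function(plates) {
    out <- lapply(split(plates, plates$group), function(d) {
        d <- d[order(d$day), , drop = FALSE]
        ev <- data.frame(time = rep(d$day, d$n_dead), event = 1L)
        last <- d[nrow(d), ]
        cens <- data.frame(time = rep(last$day, last$n_alive), event = 0L)
        res <- rbind(ev, cens)
        res$group <- d$group[1]
        res
    })
    do.call(rbind, c(out, make.row.names = FALSE))
}
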