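#' Build referral networks and facility roles
#'
#' Groups facilities into referral networks from their single survey-reported
#' referral destination: one network per facility that receives at least one
#' link, whose members are the receiving facility plus every facility
#' referring to it.
#'
#' Roles: a facility is `RECEIVING` if at least one other facility refers to
#' it (this takes precedence if it also refers onward), `REFERRING` if it
#' reports a destination, `STANDALONE` otherwise. Referral chains (a refers
#' to b, b refers onward) are structurally allowed but raised as a warning,
#' since surveyed networks are star-shaped; a cycle is an error.
#'
#' The result is independent of the input row order (networks sorted by
#' receiving id, members sorted within each network).
#'
#' @param facilities a `facility_survey` data frame with validated
#'   `refers_to` links.
#' @return a list of class `referral_networks` with elements
#'   \describe{
#'     \item{networks}{data frame: `receiving_id`, `size`, `member_ids`
#'       (list column, includes the receiving facility).}
#'     \item{roles}{data frame: `facility_id`, `role`.}
#'   }
#' @export
build_networks <- function(facilities) {
  ids <- facilities$facility_id
  dest <- setNames(facilities$refers_to, ids)

  # cycle detection in the functional graph id -> refers_to
  for (start in ids[!is.na(dest)]) {
    seen <- character()
    cur <- start
    while (!is.na(dest[[cur]])) {
      if (cur %in% seen) {
        cyc <- seen[which(seen == cur):length(seen)]
        stop_ra(sprintf("referral cycle: %s",
                        paste(c(cyc, cur), collapse = " -> ")),
                "ra_cycle_error")
      }
      seen <- c(seen, cur)
      cur <- dest[[cur]]
      if (!cur %in% ids) break
    }
  }

  receiving <- sort(unique(dest[!is.na(dest)]))
  refers <- !is.na(dest)
  chained <- intersect(receiving, ids[refers])
  if (length(chained) > 0) {
    warn_ra(sprintf(
      "referral chain(s): receiving facility(ies) %s also refer onward",
      paste(chained, collapse = ", ")), "ra_chain_warning")
  }

  role <- ifelse(ids %in% receiving, "RECEIVING",
                 ifelse(refers, "REFERRING", "STANDALONE"))
  roles <- data.frame(facility_id = sort(ids),
                      role = role[order(ids)], stringsAsFactors = FALSE)

  networks <- data.frame(receiving_id = receiving,
                         size = rep(NA_integer_, length(receiving)),
                         stringsAsFactors = FALSE)
  networks$member_ids <- lapply(receiving, function(rid) {
    sort(unique(c(rid, ids[refers & dest == rid])))
  })
  networks$size <- vapply(networks$member_ids, length, integer(1))
  structure(list(networks = networks, roles = roles),
            class = "referral_networks")
}

#' @export
print.referral_networks <- function(x, ...) {
  cat(sprintf("%d referral network(s); roles: %s\n",
              nrow(x$networks),
              paste(sprintf("%s=%d", names(table(x$roles$role)),
                            table(x$roles$role)), collapse = ", ")))
  for (i in seq_len(nrow(x$networks))) {
    cat(sprintf("  %s: %d members\n", x$networks$receiving_id[i],
                x$networks$size[i]))
  }
  invisible(x)
}

#' Audit referral rationality
#'
#' A referral configuration is rational for difficult removals when the
#' facilities that must absorb cases — receiving facilities and standalone
#' facilities that keep their own cases — are ready to manage them. This
#' audit joins network roles with readiness levels: per receiving facility
#' it reports its level (`UNKNOWN` for facilities never assessed), and over
#' all assessed receiving-or-standalone facilities it counts how many are
#' ready for regular removals and for difficult removals.
#'
#' @param networks a `referral_networks` object from [build_networks()].
#' @param readiness a `readiness_result` data frame covering every assessed
#'   facility.
#' @param facilities the `facility_survey` the networks were built from
#'   (needed to know which facilities were assessed).
#' @return a list of class `rationality_report`: `receiving` (data frame
#'   `facility_id`, `level`), `role_counts` (named integer vector), and
#'   `endpoints` (named vector: assessed receiving-or-standalone count,
#'   regular-ready count, difficult-ready count).
#' @export
assess_rationality <- function(networks, readiness, facilities) {
  roles <- networks$roles
  lev <- setNames(readiness$level, readiness$facility_id)
  assessed <- setNames(facilities$assessed, facilities$facility_id)

  miss <- facilities$facility_id[facilities$assessed &
                                   !facilities$facility_id %in% names(lev)]
  if (length(miss) > 0) {
    stop_ra(sprintf("no readiness result for assessed facility(ies): %s",
                    paste(miss, collapse = ", ")), "ra_coverage_error")
  }

  recv_ids <- roles$facility_id[roles$role == "RECEIVING"]
  receiving <- data.frame(
    facility_id = recv_ids,
    level = ifelse(assessed[recv_ids], lev[recv_ids], "UNKNOWN"),
    stringsAsFactors = FALSE)

  endpoint_ids <- roles$facility_id[roles$role %in%
                                      c("RECEIVING", "STANDALONE")]
  endpoint_ids <- endpoint_ids[assessed[endpoint_ids]]
  endpoint_lev <- lev[endpoint_ids]

  structure(list(
    receiving = receiving,
    role_counts = c(table(factor(roles$role, levels = c("REFERRING",
                                                        "RECEIVING",
                                                        "STANDALONE")))),
    endpoints = c(n_assessed = length(endpoint_ids),
                  regular_ready = sum(ready_at(endpoint_lev, "REGULAR")),
                  difficult_ready = sum(ready_at(endpoint_lev, "DIFFICULT")))
  ), class = "rationality_report")
}

#' @export
print.rationality_report <- function(x, ...) {
  rc <- x$role_counts
  cat(sprintf("Roles: %d referring, %d receiving, %d standalone\n",
              rc[["REFERRING"]], rc[["RECEIVING"]], rc[["STANDALONE"]]))
  cat("Receiving facility readiness:\n")
  for (i in seq_len(nrow(x$receiving))) {
    cat(sprintf("  %s: %s\n", x$receiving$facility_id[i], x$receiving$level[i]))
  }
  e <- x$endpoints
  cat(sprintf(paste0("Of %d assessed receiving/standalone facilities, ",
                     "%d ready for regular removals, %d for difficult\n"),
              e[["n_assessed"]], e[["regular_ready"]], e[["difficult_ready"]]))
  invisible(x)
}
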