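# Straight-line re-implementation of the per-shift fill rules, written
# independently of the engine (scalar, one block moved at a time) and used
# only as an oracle. Rules: trigger when the relative shortfall strictly
# exceeds the tolerance; float within the specialty group from units with
# any true surplus (donor never drops below its own requirement, recipient
# stops once at or above requirement), recipients in decreasing-shortfall
# order, donors in decreasing-initial-surplus order, ties broken by unit
# id; then request the minimum number of half-shift blocks covering the
# residual shortfall, each filled by the bank with probability p_bank and
# otherwise re-requested once from the agency with probability p_agency.
oracle_fill <- function(required, available, group, tolerance, block_hours,
                        allow_float, p_bank, p_agency, u_bank, u_agency,
                        unit_ids) {
  n <- length(required)
  trig <- logical(n)
  for (i in seq_len(n)) {
    if (required[i] > 0 &&
        (required[i] - available[i]) / required[i] > tolerance) {
      trig[i] <- TRUE
    }
  }
  fin <- fout <- rep(0, n)
  if (allow_float) {
    for (g in unique(group)) {
      members <- which(group == g)
      if (length(members) < 2L || !any(trig[members])) next
      donors <- members[available[members] - required[members] >=
                          block_hours - 1e-9]
      donors <- donors[order(-(available[donors] - required[donors]),
                             unit_ids[donors])]
      donor_blocks <- floor((available[donors] - required[donors]) /
                              block_hours + 1e-9)
      recips <- members[trig[members]]
      recips <- recips[order(-(required[recips] - available[recips]),
                             unit_ids[recips])]
      for (r in recips) {
        for (di in seq_along(donors)) {
          d <- donors[di]
          if (d == r) next
          # move one block at a time until the recipient reaches its
          # requirement or this donor runs out
          while (donor_blocks[di] >= 1 &&
                 available[r] + fin[r] < required[r] - 1e-9) {
            fin[r] <- fin[r] + block_hours
            fout[d] <- fout[d] + block_hours
            donor_blocks[di] <- donor_blocks[di] - 1
          }
          if (available[r] + fin[r] >= required[r] - 1e-9) break
        }
      }
    }
  }
  bank <- agency <- rep(0, n)
  for (i in seq_len(n)) {
    if (!trig[i]) next
    short <- required[i] - (available[i] - fout[i] + fin[i])
    if (short <= 1e-9) next
    blocks <- ceiling(short / block_hours - 1e-9)
    for (j in seq_len(blocks)) {
      if (u_bank[i, j] < p_bank) {
        bank[i] <- bank[i] + block_hours
      } else if (u_agency[i, j] < p_agency) {
        agency[i] <- agency[i] + block_hours
      }
    }
  }
  achieved <- available - fout + fin + bank + agency
  list(floated_in = fin, floated_out = fout, bank_hours = bank,
       agency_hours = agency, achieved = achieved, triggered = trig)
}
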