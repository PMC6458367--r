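# Shared fixtures: the two-game free-throw example and random small
# trajectory sets.

worked_alphabet <- function() alphabet("-+")

worked_text <- function() "+-++-++\n+--+-+++++-"

worked_trajs <- function() parse_trajectories(worked_text(), worked_alphabet())

# A random small trajectory set: M in 2..3 states, J trajectories of lengths
# 1..Lmax.  Draws from the current RNG stream.
random_trajs <- function(J = sample(1:5, 1), M = sample(2:3, 1), Lmax = 12) {
  ab <- alphabet(letters[seq_len(M)])
  seqs <- lapply(seq_len(J), function(j)
    sample(ab$symbols, sample.int(Lmax, 1L), replace = TRUE))
  trajectory_set(seqs, ab)
}
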