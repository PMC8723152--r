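#!/usr/bin/env bash
# Homology-search template for one bundle of candidate IGRs.
# Fill in the placeholders (or pass a templateConfig when exporting):
#   {DB}     - path to the microbial-IGR sequence database (cmsearch/nhmmer
#              target, or a BLAST database for blastn)
#   {CPUS}   - number of worker CPUs
#   {EVALUE} - reporting e-value threshold
#
# Each candidate FASTA in this bundle seeds one independent search; the
# hits collected for a candidate form its draft motif for alignment and
# covariation analysis downstream.
set -euo pipefail

DB="{DB}"
CPUS="{CPUS}"
EVALUE="{EVALUE}"

for query in *.fasta; do
    name="${query%.fasta}"
    nhmmer --cpu "$CPUS" -E "$EVALUE" --tblout "${name}.tbl" \
        -A "${name}.sto" "$query" "$DB" > "${name}.out"
done
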