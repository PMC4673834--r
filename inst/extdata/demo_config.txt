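# Demo run: fully simulated two-chromosome 1-Mb genome with planted truth.
simulate = TRUE
seed = 1
n_chromosomes = 2
chrom_length = 500000
n_sites = 200
frac_shared = 0.6
frac_a_only = 0.2
frac_b_only = 0.2
enrichment = 30
background_rate = 1
nb_dispersion = 0.2
repeat_fraction = 0.1
caller_sensitivity = 0.9
caller_fp_rate = 2
caller_jitter_sd = 30
n_genes = 30
with_sequence = TRUE

# stage parameters (standard defaults, spelled out for auditability)
extension = 200
min_support = 2
min_length = 150
min_reads = 10
min_fc = 2
max_q = 0.01
pairing_distance = 250
half_window = 500
subwindow = 25
k = 3
motif = CTGN(6-8)WGATAR
motif_width = 200
max_masked = 150
max_gene_distance = 1000000
proximal_distance = 5000
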