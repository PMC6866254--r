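# Rainbow trout IGHV gene placement counts per locus region: genes upstream
# of the functional tau-cluster constant gene, and genes between that
# cluster and the mu/delta cluster.
species	chromosome	locus_id	region	n_genes
Oncmyk	Chr13	A	upstream_tau_cluster	44
Oncmyk	Chr13	A	between_tau_and_mu_clusters	5
Oncmyk	Chr12	B	upstream_tau_cluster	70
Oncmyk	Chr12	B	between_tau_and_mu_clusters	10
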