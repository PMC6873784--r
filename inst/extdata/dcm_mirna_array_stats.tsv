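systematic_name	p_value	fold_change	regulation
hsa-miR-144-3p	2.57E-05	212.8677	down
hsa-miR-144-5p	3.18E-06	111.2795	down
hsa-miR-16-2-3p	0.047548	8.311692	down
hsa-miR-21-3p	0.032982	22.15763	Up
hsa-miR-21-5p	0.007706	2.248547	Up
hsa-miR-338-3p	0.030864	3.282057	down
hsa-miR-363-3p	0.006185	3.361872	down
hsa-miR-451a	3.08E-04	7.406941	down
hsa-miR-551b-3p	0.006586	5.052964	down
hsa-miR-770-5p	0.00854	20.36452	Up
hsa-miR-9-3p	1.55E-05	71.27749	down
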