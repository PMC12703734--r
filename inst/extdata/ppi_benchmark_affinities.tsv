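# Experimental binding free energies of the 20-complex protein-protein
# benchmark set (kcal/mol, derived from published K_D/K_i/IC50 values).
pdb_id	value	kind
1ACB	-13.1	DG
1ZHI	-9.1	DG
1AVX	-12.5	DG
2HLE	-10.1	DG
1AY7	-13.2	DG
2HRK	-11.0	DG
1BVN	-15.1	DG
2OOB	-5.7	DG
1EMV	-18.6	DG
2OUL	-12.0	DG
1FLE	-12.3	DG
2SIC	-13.8	DG
1GLA	-6.8	DG
2SNI	-16.0	DG
1KAC	-10.7	DG
2UUY	-11.3	DG
1R0R	-14.2	DG
3BZD	-9.6	DG
1YVB	-11.2	DG
3SGB	-14.5	DG
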