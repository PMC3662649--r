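gene_id	original_association	pair_group	pair_partner
RTN4RL1	good	mixed	unknown
LGP2	good	mixed	unknown
MS4A7	good	mixed	unknown
GSTM3	good	mixed	unknown
OXCT1	poor	mixed	unknown
HRASLS	poor	mixed	unknown
Contig40831_RC	poor	mixed	unknown
MELK	poor	mixed	unknown
GPR180	poor	poor_only	unknown
DTL	poor	poor_only	unknown
IGFBP5	poor	poor_only	unknown
SERF1A	poor	poor_only	unknown
GNAZ	poor	poor_only	unknown
RFC4	poor	poor_only	unknown
CDCA7	poor	poor_only	unknown
UCHL5	poor	poor_only	unknown
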