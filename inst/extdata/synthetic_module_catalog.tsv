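module_id	definition_text
M90001	K01601 K01602
M90002	K01601+K01602
M90003	(K00855,K00856) K01100 K03841
M90004	K02703+K02704+K02705+K02706 K02711+K02712
M90005	K02689+K02690-K02691 K02692
M90006	(K02108+K02109+K02110,K02111+K02112)
M90007	K00239 K00240 K00241 (K00242,K00243)
M90008	K01623,K01624
M90009	K00134 K00927 (K01834,K15633) K01689 K01610
M90010	K00615 (K00616,K08302) K01807
M90011	K01006,K01007
M90012	K02637+K02638+K02639-K02640
M90013	K01952 (K01915,K01950)
M90014	(K00031,K00032) K01681+K01682
M90015	K02258 K02259 K02260 K02261 K02262 K02263
M90016	K01872 K01873 K01874 K01875
M90017	(K02824,K02825) (K02826,K02827) K02828
M90018	K03231+K03232 K03233 -K03234
M90019	K00525+K00526 (K00527,K10807+K10808)
M90020	K02335 K02338+K02339 K02340
M90021	K03040+K03043+K03046-K03060 K03041
M90022	K01358+K01359 (K01419,K01420)
M90023	K02863 K02864 K02867 K02871 K02874 K02876 K02878 K02879
M90024	K02946 K02948 K02950 K02952 K02954 K02956
M90025	(K02986+K02988,K02990+K02992) K02994
M90026	K00330+K00331+K00332+K00333-K00334-K00335
M90027	K02014 (K02015,K02016) K02017+K02018
M90028	K03076 K03110+K03106 (K03210,K03217)
M90029	K01061 K01062
M90030	K00600 (K00605,K00382) K02437
M90031	K01868 K01869+K01870
M90032	(K01889,K01890) K01893
M90033	K02519 K02520 (K02356,K02357+K02358)
M90034	K03551+K03552 K03553
M90035	K00290 K00291,K00292
M90036	K02588+K02586+K02591-K02587 (K02584,K02585)
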