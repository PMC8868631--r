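taxon	supergroup
Bacteria_15	Bacteria
Bacteria_05	Bacteria
Bacteria_09	Bacteria
Bacteria_12	Bacteria
Bacteria_10	Bacteria
Bacteria_07	Bacteria
Bacteria_01	Bacteria
Bacteria_16	Bacteria
Bacteria_03	Bacteria
Bacteria_11	Bacteria
Bacteria_04	Bacteria
Bacteria_02	Bacteria
Bacteria_14	Bacteria
Bacteria_13	Bacteria
Bacteria_06	Bacteria
Bacteria_17	Bacteria
Bacteria_08	Bacteria
Archaea_04	Archaea
Archaea_01	Archaea
Archaea_06	Archaea
Archaea_05	Archaea
Archaea_03	Archaea
Archaea_02	Archaea
Discoba_07	Discoba
Discoba_02	Discoba
Discoba_04	Discoba
Discoba_03	Discoba
Discoba_05	Discoba
Discoba_06	Discoba
Discoba_01	Discoba
Metamonada_02	Metamonada
Metamonada_01	Metamonada
SAR_08	SAR
SAR_04	SAR
SAR_07	SAR
SAR_09	SAR
SAR_12	SAR
SAR_14	SAR
SAR_01	SAR
SAR_03	SAR
SAR_05	SAR
SAR_02	SAR
SAR_13	SAR
SAR_11	SAR
SAR_06	SAR
SAR_10	SAR
Archaeplastida_02	Archaeplastida
Archaeplastida_06	Archaeplastida
Archaeplastida_03	Archaeplastida
Archaeplastida_05	Archaeplastida
Archaeplastida_04	Archaeplastida
Archaeplastida_01	Archaeplastida
Amorphea_17	Amorphea
Amorphea_33	Amorphea
Amorphea_32	Amorphea
Amorphea_26	Amorphea
Amorphea_24	Amorphea
Amorphea_01	Amorphea
Amorphea_07	Amorphea
Amorphea_03	Amorphea
Amorphea_36	Amorphea
Amorphea_21	Amorphea
Amorphea_14	Amorphea
Amorphea_30	Amorphea
Amorphea_12	Amorphea
Amorphea_16	Amorphea
Amorphea_29	Amorphea
Amorphea_25	Amorphea
Amorphea_05	Amorphea
Amorphea_10	Amorphea
Amorphea_28	Amorphea
Amorphea_34	Amorphea
Amorphea_02	Amorphea
Amorphea_22	Amorphea
Amorphea_09	Amorphea
Amorphea_23	Amorphea
Amorphea_31	Amorphea
Amorphea_20	Amorphea
Amorphea_04	Amorphea
Amorphea_06	Amorphea
Amorphea_19	Amorphea
Amorphea_08	Amorphea
Amorphea_11	Amorphea
Amorphea_13	Amorphea
Amorphea_27	Amorphea
Amorphea_35	Amorphea
Amorphea_18	Amorphea
Amorphea_15	Amorphea
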