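((((((Bacteria_15:0.2483004127,Bacteria_05:0.3853622214)n6:0.464471828,(Bacteria_09:0.474723543,(Bacteria_12:0.2431350022,Bacteria_10:0.1467844085)n8:0.3198710305)n7:0.4197665892)n5:0.4036612566,(Bacteria_07:0.1525438454,Bacteria_01:0.2209657818)n9:0.2945488472)n4:0.2001363852,(((Bacteria_16:0.2612499648,Bacteria_03:0.1387794316)n12:0.4171013592,Bacteria_11:0.07104091478)n11:0.2623778371,(Bacteria_04:0.4808755747,((Bacteria_02:0.2148195653,(Bacteria_14:0.1390507305,((Bacteria_13:0.3192187168,Bacteria_06:0.363590517)n18:0.1268768163,Bacteria_17:0.2269247276)n17:0.3486904504)n16:0.3107267054)n15:0.06380540503,Bacteria_08:0.1797065997)n14:0.08496316815)n13:0.1682792212)n10:0.105748255)n3:0.225819,(((Archaea_04:0.3332193551,Archaea_01:0.1788931487)n21:0.1782111219,Archaea_06:0.2521773129)n20:0.2735631188,(Archaea_05:0.09550779135,(Archaea_03:0.2926529838,Archaea_02:0.1142841547)n23:0.454047035)n22:0.4884288269)n19:0.222638)n2:0.152506,(((((Discoba_07:0.4674432661,(Discoba_02:0.4239162423,Discoba_04:0.1155219239)n29:0.331760158)n28:0.06028953108,Discoba_03:0.4383590214)n27:0.09848212278,(Discoba_05:0.2289054676,Discoba_06:0.08661690612)n30:0.2000737685)n26:0.3244242495,Discoba_01:0.3981747136)n25:0.401403,((Metamonada_02:0.4698416662,Metamonada_01:0.1355142955)n32:0.108179,(((((SAR_08:0.2592114159,SAR_04:0.1624000725)n37:0.1321144808,SAR_07:0.1459995148)n36:0.3572561984,SAR_09:0.09003121256)n35:0.079260779,(((SAR_12:0.22764245,(SAR_14:0.2170820511,SAR_01:0.3079854993)n41:0.3337940744)n40:0.15788613,((SAR_03:0.2953572957,SAR_05:0.2848684605)n43:0.3945891571,SAR_02:0.1604697781)n42:0.2043305881)n39:0.18993209,(SAR_13:0.4070926006,(SAR_11:0.4715610885,(SAR_06:0.3205617782,SAR_10:0.07517281785)n46:0.1750820756)n45:0.1732243089)n44:0.2896368513)n38:0.114472454)n34:0.100829,(((Archaeplastida_02:0.3082621953,(Archaeplastida_06:0.3931170751,(Archaeplastida_03:0.2161864822,Archaeplastida_05:0.3493314088)n51:0.4857835372)n50:0.2455167478)n49:0.4976245794,(Archaeplastida_04:0.4297415473,Archaeplastida_01:0.09923170297)n52:0.2228614369)n48:0.147091,((((((Amorphea_17:0.3497296009,Amorphea_33:0.05118620337)n58:0.2370598842,((Amorphea_32:0.3888111151,Amorphea_26:0.1073701482)n60:0.330852692,(Amorphea_24:0.2212096917,Amorphea_01:0.1542244309)n61:0.4491091208)n59:0.3038741794)n57:0.3835732486,((Amorphea_07:0.4820789581,Amorphea_03:0.2073684778)n63:0.4937545546,Amorphea_36:0.3183162122)n62:0.2048447523)n56:0.4368409399,(Amorphea_21:0.1726914638,(Amorphea_14:0.3322730009,Amorphea_30:0.2460054771)n65:0.3096258302)n64:0.4469104391)n55:0.3893927601,(((Amorphea_12:0.4159061369,Amorphea_16:0.2080435159)n68:0.1250613836,Amorphea_29:0.05647184231)n67:0.257877932,((Amorphea_25:0.1070424758,Amorphea_05:0.125947522)n70:0.1895826494,((Amorphea_10:0.1260732641,Amorphea_28:0.418700385)n72:0.1965077444,((Amorphea_34:0.2905739058,((Amorphea_02:0.3970801089,Amorphea_22:0.3624690747)n76:0.4353410331,Amorphea_09:0.385857557)n75:0.2823584156)n74:0.2473565103,(Amorphea_23:0.2928217969,(Amorphea_31:0.4607385033,Amorphea_20:0.1352235842)n78:0.4632389469)n77:0.07852029254)n73:0.3045322165)n71:0.3060251238)n69:0.4502287928)n66:0.1647161278)n54:0.4058949118,((Amorphea_04:0.4107406457,Amorphea_06:0.3012841989)n80:0.1532907217,((((Amorphea_19:0.28266842,Amorphea_08:0.2014082681)n84:0.2393394357,(Amorphea_11:0.4427894415,Amorphea_13:0.1699226675)n85:0.4054200529)n83:0.2183422623,(Amorphea_27:0.1913127701,(Amorphea_35:0.3209697121,Amorphea_18:0.327070834)n87:0.3362456542)n86:0.4426963302)n82:0.4365285927,Amorphea_15:0.333947634)n81:0.4269860252)n79:0.09425999)n53:0.497654)n47:0.229783)n33:0.360394)n31:0.496641)n24:0.460291)n1;
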