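taxon,region,order_or_class,lc50,abundance
synthetic Baetis A,WET,Ephemeroptera,5.4,abundant
synthetic Baetis B,WET,Ephemeroptera,2.5–5,abundant
synthetic Caenis A,WET,Ephemeroptera,10.8,rare
synthetic Hydropsyche A,WET,Trichoptera,16.9,abundant
synthetic Leuctra A,WET,Plecoptera,9.1,rare
synthetic Gammarus A,WET,Amphipoda,27.5–35,abundant
synthetic Chironomus A,WET,Diptera,20–27.5,abundant
synthetic Simulium A,WET,Diptera,12.4,abundant
synthetic Micronecta A,WET,Hemiptera,26.2,rare
synthetic Dugesia A,WET,Turbellaria,11.9,rare
synthetic Physa A,WET,Gastropoda,12.3,abundant
synthetic Dytiscus A,WET,Coleoptera,>55,rare
synthetic Lestes A,WET,Odonata,30.6,rare
synthetic Hydrachna A,WET,Hydracarina,19.3,rare
synthetic Erpobdella A,WET,Hirudinea,15.1,rare
synthetic Atyaephyra A,ARID,Decapoda,>55,rare
synthetic Baetis C,ARID,Ephemeroptera,10.3,abundant
synthetic Cloeon A,ARID,Ephemeroptera,15–20,abundant
synthetic Orthetrum A,ARID,Odonata,41.6,rare
synthetic Berosus A,ARID,Coleoptera,37.8,rare
synthetic Culex A,ARID,Diptera,35–45,abundant
synthetic Anisops A,ARID,Hemiptera,27.8,abundant
synthetic Melanoides A,ARID,Gastropoda,21.1,abundant
synthetic Gammarus B,ARID,Amphipoda,>45,rare
synthetic Hydropsyche B,ARID,Trichoptera,12.3,abundant
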