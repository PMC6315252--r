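{
  "testimonies_or_real_life_stories": ["história", "histórias", "depoimento", "depoimentos", "relato", "relatos", "superação", "vivência", "experiência", "venci", "luta", "guerreira", "guerreiro"],
  "solidarity": ["doador", "doadores", "doadora", "doadoras", "doação", "doações", "doar", "doe", "sangue", "medula", "cabelo", "solidariedade", "ajude", "arrecadação", "voluntário", "voluntários", "voluntária", "voluntárias"],
  "anniversaries": ["aniversário", "aniversários", "dia", "comemoração", "comemorações", "parabéns", "celebrar", "celebração", "aniversariante", "homenagem"],
  "science_and_health": ["pesquisa", "pesquisas", "estudo", "estudos", "científico", "científica", "descoberta", "descobertas", "tratamento", "tratamentos", "terapia", "terapias", "cientista", "cientistas", "universidade", "artigo", "imunoterapia"],
  "events": ["evento", "eventos", "palestra", "palestras", "corrida", "caminhada", "inscrição", "inscrições", "workshop", "encontro", "festival", "bazar", "feira"],
  "institutional": ["instituição", "instituto", "hospital", "fundação", "equipe", "missão", "sede", "unidade", "serviço", "atendimento", "funcionários", "parceria"],
  "risk_factors": ["cigarro", "cigarros", "fumo", "tabagismo", "fumar", "álcool", "obesidade", "sedentarismo", "risco", "riscos", "prevenção", "prevenir", "hábito", "hábitos"],
  "beauty": ["maquiagem", "beleza", "lenço", "lenços", "peruca", "perucas", "batom", "penteado", "penteados", "turbante", "turbantes", "moda", "autoestima"]
}
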