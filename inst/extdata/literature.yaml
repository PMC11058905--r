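# Published census values carried as inputs (never recomputed here):
# worked-example demand, POC export ranges and layer silica budgets.
global:
  annual_carbon_demand_PgC_y: 0.46
  poc_export_PgC_y: [5.0, 12.0]
  poc_export_source: "global export syntheses"
southern_ocean:
  poc_export_PgC_y: [0.62, 1.3]
  poc_export_source: "Southern Ocean export estimates"
bsi_stock_Tg:
  epipelagic: 0.34
  mesopelagic: 3.91
bsi_production_Tg_y:
  epipelagic: 0.70
  mesopelagic: 3.96
turnover_days:
  q1: 8.4
  median: 10.9
  q3: 17.4
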